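# Reference-cohort fixture. The source study's patient-level data are not
# deposited; what it prints are category counts (per-gene cohort sizes,
# mutation-type by RAML tallies, functional-domain by RAML tallies, sex by
# RAML). paper_cohort() rebuilds a deterministic 261-record cohort whose
# variants, run through the package's own parsing/classification/annotation
# stack, reproduce those printed counts; paper_counts() exposes the printed
# 2x2 tables directly. Variant positions are synthetic (evenly spread inside
# the targeted domain/region intervals); only the category counts are data.

spread_pos <- function(n, lo, hi) {
  if (n == 0L) return(integer(0))
  as.integer(round(seq(lo, hi, length.out = n)))
}

#' Published 2x2 contingency tables of the reference cohort
#'
#' The exposure-by-RAML tables printed for the 261-patient reference cohort,
#' in the package's orientation contract (a = exposed & RAML, b = exposed &
#' no RAML, c = unexposed & RAML, d = unexposed & no RAML). Useful for
#' exercising the contingency engine directly; [paper_cohort()] reproduces
#' the same tables through the full pipeline.
#'
#' @return Named list of [table2x2()] objects.
#' @export
paper_counts <- function() {
  list(
    sex = table2x2(47, 38, 21, 42),
    gene = table2x2(22, 32, 104, 103),
    tsc1_pt = table2x2(11, 30, 11, 2),
    tsc1_nonsense = table2x2(6, 12, 16, 20),
    tsc1_frameshift = table2x2(4, 15, 18, 17),
    tsc1_large_fragment = table2x2(1, 3, 21, 29),
    tsc1_missense = table2x2(11, 2, 11, 30),
    tsc2_ccd1 = table2x2(3, 3, 93, 97),
    tsc2_ccd2 = table2x2(1, 4, 95, 96),
    tsc2_tad1 = table2x2(15, 5, 81, 95),
    tsc2_gapd = table2x2(8, 11, 88, 89),
    tsc2_tad2_cabd = table2x2(14, 13, 82, 87),
    tsc2_others = table2x2(55, 64, 41, 36)
  )
}

#' Deterministic 261-patient reference cohort fixture
#'
#' Rebuilds, as patient-level records, the reference cohort whose published
#' category counts drive the package's validation: 54 TSC1 / 207 TSC2
#' patients; per-gene mutation-type by RAML tallies; TSC2 functional-domain
#' by RAML tallies on the large-fragment-excluded set (denominators 96 RAML /
#' 100 non-RAML = 104 - 8 and 103 - 3); and the sex margin (85 female of
#' whom 47 RAML, 63 male of whom 21 RAML, 113 of unknown sex). Variant
#' positions within each targeted interval are synthetic and evenly spread;
#' running [analyze()] on the result reproduces the published tables.
#'
#' Two published tallies cannot be reproduced exactly because they are
#' internally inconsistent with the domain counts and coordinates (see the
#' vignette): the TSC2 RAML region split prints HID-TID/middle/GAP =
#' 41/34/21, but its own GAP-exon domains already hold 22 RAML mutations;
#' this cohort yields 40/34/22.
#'
#' @return Data frame in the standard cohort schema (`patient_id`, `gene`,
#'   `transcript`, `hgvs_c`, `hgvs_p`, `sex`, `raml`, `source`).
#' @export
#' @examples
#' coh <- paper_cohort()
#' table(coh$gene, coh$raml)
paper_cohort <- function() {
  rows <- vector("list", 300L)
  k <- 0L
  add <- function(gene, raml, hgvs_c, hgvs_p = NA_character_) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(gene = gene, raml = raml, hgvs_c = hgvs_c,
                             hgvs_p = hgvs_p, stringsAsFactors = FALSE)
  }
  ms <- function(gene, raml, pos) {
    for (p in pos) add(gene, raml, sprintf("c.%dG>A", p),
                       sprintf("p.(Gly%dAsp)", ceiling(p / 3)))
  }
  ns <- function(gene, raml, pos) {
    for (p in pos) add(gene, raml, sprintf("c.%dG>A", p),
                       sprintf("p.(Trp%dTer)", ceiling(p / 3)))
  }
  fs <- function(gene, raml, pos) {
    for (p in pos) add(gene, raml, sprintf("c.%d_%ddel", p, p + 1L))
  }
  inf <- function(gene, raml, pos) {
    for (p in pos) add(gene, raml, sprintf("c.%d_%ddel", p, p + 2L))
  }
  sp <- function(gene, raml, anchor, off = 1L) {
    for (i in seq_along(anchor)) {
      add(gene, raml, sprintf("c.%d%+dG>A", anchor[i], off))
    }
  }
  lf <- function(gene, raml, s, e, dup = FALSE) {
    add(gene, raml, sprintf("c.%d_%d%s", s, e, if (dup) "dup" else "del"))
  }

  ## ---- TSC1, RAML (22): 11 missense, 6 nonsense, 4 frameshift, 1 large ----
  ms("TSC1", TRUE, c(390, 420))                    # TMD (aa 127-144)
  ms("TSC1", TRUE, c(700, 800, 900))               # TID exons 8-11
  ms("TSC1", TRUE, spread_pos(6, 1240, 1850))      # N-terminal, no domain
  ns("TSC1", TRUE, spread_pos(3, 950, 1210))       # TID
  ns("TSC1", TRUE, 2250)                           # CCD (aa 730-996)
  ns("TSC1", TRUE, 3100)                           # C-terminal, exon 23
  ns("TSC1", TRUE, 300)                            # N-terminal
  fs("TSC1", TRUE, c(2400, 2600))                  # CCD
  fs("TSC1", TRUE, c(1300, 1500))                  # N-terminal
  lf("TSC1", TRUE, 151, 378)                       # exons 4-5

  ## ---- TSC1, non-RAML (32): 2 ms, 12 ns, 15 fs, 3 large ----
  ms("TSC1", FALSE, c(260, 360))
  ns("TSC1", FALSE, c(660, 720))                   # TID
  fs("TSC1", FALSE, c(1000, 1100))                 # TID
  ns("TSC1", FALSE, spread_pos(4, 2200, 2980))     # CCD
  fs("TSC1", FALSE, spread_pos(4, 2210, 2970))     # CCD
  ns("TSC1", FALSE, spread_pos(6, 1230, 1800))
  fs("TSC1", FALSE, spread_pos(7, 1300, 1840))
  fs("TSC1", FALSE, c(3040, 3400))                 # exon 23
  lf("TSC1", FALSE, 151, 378)
  lf("TSC1", FALSE, 738, 1220)                     # exons 9-11
  lf("TSC1", FALSE, 1861, 2180, dup = TRUE)        # exons 16-17

  ## ---- TSC2, RAML, non-large (96): matches the domain table exactly ----
  ms("TSC2", TRUE, spread_pos(3, 1040, 1110))      # CCD1 (aa 346-371)
  ms("TSC2", TRUE, 3040)                           # CCD2 (aa 1008-1021)
  ns("TSC2", TRUE, spread_pos(8, 3490, 3774))      # TAD1 (aa 1163-1259)
  sp("TSC2", TRUE, 3611, +1L)                      # TAD1, exon-29 donor
  fs("TSC2", TRUE, c(3500, 3600, 3700))            # TAD1
  ms("TSC2", TRUE, c(3520, 3620, 3720))            # TAD1
  ns("TSC2", TRUE, spread_pos(4, 4552, 5020))      # GAPD (aa 1517-1674)
  fs("TSC2", TRUE, spread_pos(4, 4552, 5018))      # GAPD
  fs("TSC2", TRUE, spread_pos(6, 5070, 5260))      # TAD2+CaBD (aa 1690-1755)
  ns("TSC2", TRUE, spread_pos(4, 5070, 5260))      # TAD2+CaBD
  ms("TSC2", TRUE, spread_pos(4, 5075, 5255))      # TAD2+CaBD
  # no-domain variants, HID-TID region (exons 1-22)
  fs("TSC2", TRUE, spread_pos(16, 1124, 2696))
  ns("TSC2", TRUE, spread_pos(3, 300, 1030))
  sp("TSC2", TRUE, c(480, 600, 720, 840, 1410, 1540), +1L)
  inf("TSC2", TRUE, c(310, 1000))
  ms("TSC2", TRUE, spread_pos(10, 1130, 2690))
  # no-domain variants, middle region (exons 23-33)
  fs("TSC2", TRUE, spread_pos(7, 3781, 4543))
  ns("TSC2", TRUE, c(2720, 2800))
  sp("TSC2", TRUE, c(2960, 3960, 4200), +1L)
  inf("TSC2", TRUE, c(2730, 3080))
  ms("TSC2", TRUE, spread_pos(4, 3090, 3470))

  ## ---- TSC2, RAML, large fragments (8) ----
  lf("TSC2", TRUE, 121, 360)
  lf("TSC2", TRUE, 361, 600)
  lf("TSC2", TRUE, 601, 840)
  lf("TSC2", TRUE, 841, 1035)
  lf("TSC2", TRUE, 1151, 1410)
  lf("TSC2", TRUE, 3022, 3280)
  lf("TSC2", TRUE, 4549, 4860)
  lf("TSC2", TRUE, 5161, 5424)

  ## ---- TSC2, non-RAML, non-large (100) ----
  ms("TSC2", FALSE, spread_pos(3, 1040, 1110))     # CCD1
  ms("TSC2", FALSE, c(3030, 3050))                 # CCD2
  ns("TSC2", FALSE, c(3035, 3055))                 # CCD2
  ms("TSC2", FALSE, 3520)                          # TAD1
  ns("TSC2", FALSE, c(3600, 3700))                 # TAD1
  sp("TSC2", FALSE, 3611, +2L)                     # TAD1
  fs("TSC2", FALSE, 3650)                          # TAD1
  ns("TSC2", FALSE, spread_pos(5, 4555, 5015))     # GAPD
  fs("TSC2", FALSE, spread_pos(4, 4560, 5010))     # GAPD
  ms("TSC2", FALSE, c(4600, 4900))                 # GAPD
  fs("TSC2", FALSE, spread_pos(4, 5070, 5258))     # TAD2+CaBD
  ns("TSC2", FALSE, spread_pos(4, 5072, 5256))     # TAD2+CaBD
  ms("TSC2", FALSE, spread_pos(5, 5078, 5250))     # TAD2+CaBD
  # no-domain, HID-TID
  fs("TSC2", FALSE, spread_pos(13, 1126, 2698))
  ns("TSC2", FALSE, spread_pos(4, 310, 1020))
  sp("TSC2", FALSE, c(1540, 1670, 1800, 1930, 2060, 2190, 2320, 2450,
                      2580, 2710), +1L)
  inf("TSC2", FALSE, spread_pos(4, 320, 1010))
  ms("TSC2", FALSE, spread_pos(13, 1132, 2692))
  # no-domain, middle
  fs("TSC2", FALSE, spread_pos(4, 3783, 4541))
  ns("TSC2", FALSE, c(2725, 2805))
  sp("TSC2", FALSE, c(2840, 3432, 3790), +1L)
  inf("TSC2", FALSE, c(2735, 3085))
  ms("TSC2", FALSE, spread_pos(7, 3095, 3465))
  # no-domain, GAP region tail (aa beyond CaBD)
  fs("TSC2", FALSE, 5280)
  ms("TSC2", FALSE, 5300)

  ## ---- TSC2, non-RAML, large fragments (3: two deletions, one dup) ----
  lf("TSC2", FALSE, 241, 480)
  lf("TSC2", FALSE, 1411, 1670)
  lf("TSC2", FALSE, 3433, 3790, dup = TRUE)

  coh <- do.call(rbind, rows[seq_len(k)])
  coh <- coh[order(match(coh$gene, c("TSC1", "TSC2"))), , drop = FALSE]
  stopifnot(nrow(coh) == 261L,
            sum(coh$gene == "TSC1") == 54L,
            sum(coh$gene == "TSC2") == 207L,
            sum(coh$raml) == 126L)

  # Sex margin: 85 female (47 RAML), 63 male (21 RAML), 113 unknown (58 RAML)
  coh$sex <- NA_character_
  i_raml <- which(coh$raml)
  i_no <- which(!coh$raml)
  coh$sex[i_raml] <- rep(c("female", "male", "unknown"), c(47L, 21L, 58L))
  coh$sex[i_no] <- rep(c("female", "male", "unknown"), c(38L, 42L, 55L))

  coh$patient_id <- sprintf("P%03d", seq_len(nrow(coh)))
  coh$transcript <- ifelse(coh$gene == "TSC1", "NM_000368.4", "NM_000548.3")
  coh$source <- "reference-cohort fixture"
  rownames(coh) <- NULL
  coh[, COHORT_COLUMNS]
}
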
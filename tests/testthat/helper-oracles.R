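# Shared oracles and fixtures, rebuilt in code at test time.

ref_tsc1 <- load_reference("TSC1")
ref_tsc2 <- load_reference("TSC2")

# Independent Fisher oracle: exhaustive enumeration of all tables with the
# observed margins, probabilities from log-binomial coefficients (not the
# dhyper route the implementation uses).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(r1, supp) + lchoose(n - r1, c1 - supp) - lchoose(n, c1)
  p <- exp(logp)
  min(1, sum(p[p <= p[match(a, supp)] * (1 + 1e-7)]))
}

# Brute-force domain oracle: test every residue of the span against every
# domain interval (exon intervals for exon-only domains).
domain_oracle <- function(res_start, res_end, ex_start, ex_end, ref) {
  dom <- ref$domains
  hit <- character(0)
  for (j in seq_len(nrow(dom))) {
    if (is.finite(dom$aa_start[j])) {
      if (any(seq(res_start, res_end) >= dom$aa_start[j] &
                seq(res_start, res_end) <= dom$aa_end[j])) {
        hit <- c(hit, dom$name[j])
      }
    } else {
      if (any(seq(ex_start, ex_end) >= dom$exon_start[j] &
                seq(ex_start, ex_end) <= dom$exon_end[j])) {
        hit <- c(hit, dom$name[j])
      }
    }
  }
  if (any(hit %in% c("TAD2", "CaBD"))) {
    hit <- c(setdiff(hit, c("TAD2", "CaBD")), "TAD2+CaBD")
  }
  hit
}

random_table <- function(max_cell = 30L) {
  cells <- sample.int(max_cell, 4L, replace = TRUE)
  table2x2(cells[1], cells[2], cells[3], cells[4])
}

# Agreement with a published (rounded) value: half a unit in the last printed
# place, plus 0.1% relative slack for the CI z-value convention.
expect_printed <- function(computed, printed, digits = 3) {
  expect_true(
    abs(computed - printed) <= 0.5 * 10^(-digits) + 1e-3 * abs(printed),
    label = sprintf("computed %.6g vs printed %.6g", computed, printed))
}

# One comparison row from a report, by label (and optionally gene).
report_row <- function(report, label, gene = NULL) {
  cmp <- report$comparisons
  sel <- cmp$label == label
  if (!is.null(gene)) sel <- sel & cmp$gene %in% gene
  stopifnot(sum(sel) == 1L)
  cmp[sel, , drop = FALSE]
}
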
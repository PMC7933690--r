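#' Map CDS positions to exon numbers
#'
#' Each coding CDS position lies in exactly one exon (the exon spans tile the
#' CDS); intronic-offset positions map to the exon anchoring their coding
#' position.
#'
#' @param pos Integer vector of CDS positions.
#' @param ref A `tsc_reference`.
#' @return Integer vector of exon numbers.
#' @export
#' @examples
#' cds_to_exon(3489, load_reference("TSC2"))  # exon 29
cds_to_exon <- function(pos, ref) {
  if (any(!is.finite(pos)) || any(pos < 1L) || any(pos > ref$cds_length)) {
    tscgp_error("tscgp_range_error",
                sprintf("CDS position outside [1, %d]", ref$cds_length))
  }
  cex <- coding_exons(ref)
  idx <- findInterval(pos, cex$cds_start)
  as.integer(cex$exon[idx])
}

#' Assign functional domains to residue/exon spans
#'
#' A variant is counted in every domain whose amino-acid interval intersects
#' its residue span; TID, which has no published amino-acid interval, is
#' matched by exon overlap instead. Hits on the overlapping tuberin domains
#' TAD2 and CaBD are reported under the merged label `"TAD2+CaBD"` (the two
#' are indistinguishable for variants in the shared residues 1740-1744 and
#' are analysed as one group). With `propagate = TRUE`, truncating variants
#' additionally hit every domain downstream of their start residue
#' ("potentially affected" in the loss-propagation sense); the default counts
#' each lesion at its own position only.
#'
#' @param residue_start,residue_end Integer vectors (residue span per variant).
#' @param exon_start,exon_end Integer vectors (exon span per variant).
#' @param ref A `tsc_reference`.
#' @param merge_tad2_cabd Report TAD2/CaBD hits under the merged label.
#' @param propagate Logical vector (recycled): propagate hits downstream.
#' @return List of character vectors of domain labels (possibly empty).
#' @export
assign_domains <- function(residue_start, residue_end, exon_start, exon_end,
                           ref, merge_tad2_cabd = TRUE, propagate = FALSE) {
  n <- length(residue_start)
  propagate <- rep_len(propagate, n)
  dom <- ref$domains
  hits <- matrix(FALSE, n, nrow(dom))
  for (j in seq_len(nrow(dom))) {
    if (is.finite(dom$aa_start[j]) && is.finite(dom$aa_end[j])) {
      hit <- residue_start <= dom$aa_end[j] & residue_end >= dom$aa_start[j]
      hit <- hit | (propagate & dom$aa_end[j] >= residue_start)
    } else {
      hit <- exon_start <= dom$exon_end[j] & exon_end >= dom$exon_start[j]
      hit <- hit | (propagate & dom$exon_end[j] >= exon_start)
    }
    hits[, j] <- hit
  }
  labels <- dom$name
  lapply(seq_len(n), function(i) {
    hit <- labels[hits[i, ]]
    if (merge_tad2_cabd && any(hit %in% c("TAD2", "CaBD"))) {
      hit <- c(setdiff(hit, c("TAD2", "CaBD")), "TAD2+CaBD")
    }
    hit
  })
}

#' Assign the region label for a variant's exon span
#'
#' Every coding variant belongs to exactly one region (N-/C-terminal for
#' TSC1 by the exon-15 boundary; HID-TID / middle / GAP for TSC2). Variants
#' spanning several exons (large fragments) are assigned by rule — default
#' the region of the 5'-most affected exon — and flagged ambiguous when their
#' two end exons fall in different regions.
#'
#' @param exon_start,exon_end Integer vectors of first/last affected exon.
#' @param ref A `tsc_reference`.
#' @param rule `"five_prime"` (default) or `"three_prime"`.
#' @return Data frame with columns `region` and `region_ambiguous`.
#' @export
assign_region <- function(exon_start, exon_end, ref,
                          rule = c("five_prime", "three_prime")) {
  rule <- match.arg(rule)
  reg <- ref$regions
  lookup <- function(e) {
    idx <- findInterval(e, reg$exon_start)
    bad <- idx < 1L | e > reg$exon_end[pmax(idx, 1L)]
    if (any(bad)) {
      tscgp_error("tscgp_range_error",
                  sprintf("exon %s not covered by any region",
                          paste(unique(e[bad]), collapse = ", ")))
    }
    reg$name[idx]
  }
  r_start <- lookup(exon_start)
  r_end <- lookup(exon_end)
  data.frame(
    region = if (rule == "five_prime") r_start else r_end,
    region_ambiguous = r_start != r_end,
    stringsAsFactors = FALSE
  )
}

#' Annotate a cohort of variant records
#'
#' Runs the full annotation stack on a cohort data frame: HGVS parsing,
#' mutation-type and PT/NT classification (using the record's protein-level
#' note as the declared consequence), exon mapping, residue span, domain set
#' and region. Records of both genes may be mixed; row order is preserved.
#'
#' @param records Data frame with at least `gene`, `hgvs_c`; optionally
#'   `hgvs_p` and any phenotype columns (carried through).
#' @param config A [classification_config()].
#' @param region_rule Passed to [assign_region()].
#' @param propagate_domains Passed to [assign_domains()] (`propagate` for
#'   truncating variants).
#' @param reference_dir Optional directory of replacement reference tables.
#' @return The input data frame with added columns `kind`, `cds_start`,
#'   `cds_end`, `intron_offset`, `length_change`, `mutation_type`,
#'   `low_confidence`, `truncation`, `exon_start`, `exon_end`,
#'   `residue_start`, `residue_end`, `domains` (`";"`-separated labels, `""`
#'   when none), `region`, `region_ambiguous`.
#' @export
annotate_cohort <- function(records, config = classification_config(),
                            region_rule = "five_prime",
                            propagate_domains = FALSE,
                            reference_dir = NULL) {
  stopifnot(all(c("gene", "hgvs_c") %in% names(records)))
  n <- nrow(records)
  if (n == 0L) return(records)
  if (!"hgvs_p" %in% names(records)) records$hgvs_p <- NA_character_

  add <- data.frame(
    kind = NA_character_, cds_start = NA_integer_, cds_end = NA_integer_,
    intron_offset = NA_integer_, length_change = NA_integer_,
    mutation_type = NA_character_, low_confidence = NA,
    truncation = NA_character_, exon_start = NA_integer_,
    exon_end = NA_integer_, residue_start = NA_integer_,
    residue_end = NA_integer_, domains = NA_character_,
    region = NA_character_, region_ambiguous = NA,
    stringsAsFactors = FALSE
  )[rep(1L, n), , drop = FALSE]

  for (g in intersect(c("TSC1", "TSC2"), unique(records$gene))) {
    i <- which(records$gene == g)
    ref <- load_reference(g, dir = reference_dir)
    pv <- parse_hgvs_c(records$hgvs_c[i], g, ref)
    type <- classify_mutation_type(pv, records$hgvs_p[i], ref, config)
    add$kind[i] <- pv$kind
    add$cds_start[i] <- pv$cds_start
    add$cds_end[i] <- pv$cds_end
    add$intron_offset[i] <- pv$intron_offset
    add$length_change[i] <- pv$length_change
    add$mutation_type[i] <- as.character(type)
    add$low_confidence[i] <- attr(type, "low_confidence")
    add$truncation[i] <- classify_truncation(type)
    add$exon_start[i] <- cds_to_exon(pv$cds_start, ref)
    add$exon_end[i] <- cds_to_exon(pv$cds_end, ref)
    add$residue_start[i] <- cds_to_protein(pv$cds_start, ref$cds_length)
    add$residue_end[i] <- cds_to_protein(pv$cds_end, ref$cds_length)
    doms <- assign_domains(add$residue_start[i], add$residue_end[i],
                           add$exon_start[i], add$exon_end[i], ref,
                           propagate = propagate_domains &
                             add$truncation[i] == "PT")
    add$domains[i] <- vapply(doms, paste, character(1), collapse = ";")
    regs <- assign_region(add$exon_start[i], add$exon_end[i], ref, region_rule)
    add$region[i] <- regs$region
    add$region_ambiguous[i] <- regs$region_ambiguous
  }
  bad_gene <- !(records$gene %in% c("TSC1", "TSC2"))
  if (any(bad_gene)) {
    stop("unknown gene in cohort: ", paste(unique(records$gene[bad_gene]),
                                           collapse = ", "), call. = FALSE)
  }
  rownames(records) <- NULL
  cbind(records, add, row.names = NULL)
}

has_domain <- function(domains, label) {
  vapply(strsplit(domains, ";", fixed = TRUE),
         function(d) label %in% d, logical(1))
}
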
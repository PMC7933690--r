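#' Load the packaged transcript, domain, and region tables for a TSC gene
#'
#' Reads the coding-sequence geometry (exon spans in CDS coordinates), the
#' functional-domain amino-acid/exon intervals, and the region split
#' (N-/C-terminal for TSC1; HID-TID / middle / GAP for TSC2) for one gene,
#' and validates every structural invariant before returning. The packaged
#' tables use synthetic exon boundaries constructed to be consistent with the
#' published domain placements (see the vignette); a different reference
#' directory with the same file layout can be substituted via `dir`.
#'
#' @param gene `"TSC1"` or `"TSC2"`.
#' @param dir Directory holding `transcripts.tsv`, `exons_<gene>.tsv`,
#'   `domains_<gene>.tsv` and `regions_<gene>.tsv`. Defaults to the tables
#'   shipped with the package.
#' @param cache Reuse a previously loaded copy of the packaged tables.
#' @return An object of class `tsc_reference`: a list with elements `gene`,
#'   `transcript_id`, `cds_length`, `protein_length`, `noncoding_exons`,
#'   `exons` (data frame: exon, cds_start, cds_end, coding), `domains`
#'   (name, aa_start, aa_end, exon_start, exon_end) and `regions`
#'   (name, exon_start, exon_end).
#' @seealso [validate_reference()]
#' @export
#' @examples
#' ref <- load_reference("TSC2")
#' subset(ref$domains, name == "TAD1")
load_reference <- function(gene = c("TSC1", "TSC2"), dir = NULL, cache = TRUE) {
  gene <- match.arg(gene)
  packaged <- is.null(dir)
  if (packaged) {
    key <- paste0("ref_", gene)
    if (cache && !is.null(.tscgp_env[[key]])) return(.tscgp_env[[key]])
    dir <- system.file("extdata", "reference_synthetic", package = "tscgp")
  }
  read_ref_tsv <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      stop("reference file missing: ", path, call. = FALSE)
    }
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  tx <- read_ref_tsv("transcripts.tsv")
  tx <- tx[tx$gene == gene, , drop = FALSE]
  if (nrow(tx) != 1L) {
    stop("transcripts.tsv must contain exactly one row for ", gene, call. = FALSE)
  }
  ref <- structure(
    list(
      gene = gene,
      transcript_id = tx$transcript_id,
      cds_length = as.integer(tx$cds_length),
      protein_length = as.integer(tx$protein_length),
      noncoding_exons = as.integer(tx$noncoding_exons),
      exons = read_ref_tsv(paste0("exons_", gene, ".tsv")),
      domains = read_ref_tsv(paste0("domains_", gene, ".tsv")),
      regions = read_ref_tsv(paste0("regions_", gene, ".tsv"))
    ),
    class = "tsc_reference"
  )
  problems <- validate_reference(ref)
  if (nrow(problems) > 0L) {
    stop("invalid reference tables for ", gene, ":\n",
         paste0("  - [", problems$component, " ", problems$item, "] ",
                problems$message, collapse = "\n"),
         call. = FALSE)
  }
  if (packaged && cache) .tscgp_env[[paste0("ref_", gene)]] <- ref
  ref
}

#' Check every structural invariant of a reference object
#'
#' Reporting companion to [load_reference()]: returns one row per violation
#' (empty data frame when the tables are internally consistent). Checked
#' invariants: coding exon spans are disjoint, ordered and tile
#' `[1, cds_length]` exactly; `protein_length == cds_length / 3 - 1` (stop
#' codon excluded); domain amino-acid intervals lie within the protein and,
#' translated to CDS nucleotides, within the exon range attributed to the
#' domain; regions partition the coding exons with no gap or overlap.
#'
#' @param ref A `tsc_reference` (or an equally shaped list under test).
#' @return Data frame with columns `component`, `item`, `message`.
#' @export
validate_reference <- function(ref) {
  problems <- list()
  note <- function(component, item, message) {
    problems[[length(problems) + 1L]] <<-
      data.frame(component = component, item = as.character(item),
                 message = message, stringsAsFactors = FALSE)
  }

  ex <- ref$exons
  coding <- ex[ex$coding %in% TRUE, , drop = FALSE]
  if (nrow(coding) == 0L) {
    note("exons", "-", "no coding exons")
  } else {
    coding <- coding[order(coding$exon), , drop = FALSE]
    bad_span <- which(!is.finite(coding$cds_start) | !is.finite(coding$cds_end) |
                        coding$cds_start > coding$cds_end)
    for (i in bad_span) {
      note("exons", coding$exon[i], "empty or inverted CDS span on a coding exon")
    }
    if (length(bad_span) == 0L) {
      if (coding$cds_start[1L] != 1L) {
        note("exons", coding$exon[1L], "first coding exon does not start at CDS position 1")
      }
      if (nrow(coding) > 1L) {
        gaps <- which(coding$cds_start[-1L] != coding$cds_end[-nrow(coding)] + 1L)
        for (i in gaps) {
          note("exons", coding$exon[i + 1L],
               sprintf("CDS span is not contiguous with exon %d (gap or overlap)",
                       coding$exon[i]))
        }
      }
      if (coding$cds_end[nrow(coding)] != ref$cds_length) {
        note("exons", coding$exon[nrow(coding)],
             sprintf("last coding exon ends at %d, not cds_length %d",
                     coding$cds_end[nrow(coding)], ref$cds_length))
      }
    }
  }
  nc <- ex[!(ex$coding %in% TRUE), , drop = FALSE]
  if (identical(ref$gene, "TSC1") && nrow(nc) != ref$noncoding_exons) {
    note("exons", "-", sprintf("expected %d non-coding exon rows, found %d",
                               ref$noncoding_exons, nrow(nc)))
  }

  if (ref$protein_length != ref$cds_length / 3 - 1) {
    note("transcript", ref$gene,
         sprintf("protein_length %d != cds_length/3 - 1 = %s",
                 ref$protein_length, format(ref$cds_length / 3 - 1)))
  }

  dom <- ref$domains
  for (i in seq_len(nrow(dom))) {
    has_aa <- is.finite(dom$aa_start[i]) && is.finite(dom$aa_end[i])
    if (has_aa) {
      if (dom$aa_start[i] < 1L || dom$aa_start[i] > dom$aa_end[i] ||
            dom$aa_end[i] > ref$protein_length) {
        note("domains", dom$name[i],
             sprintf("aa interval %d-%d outside [1, %d] or inverted",
                     dom$aa_start[i], dom$aa_end[i], ref$protein_length))
        next
      }
      # residue i occupies CDS nucleotides 3*(i-1)+1 .. 3*i
      nt_lo <- 3L * (dom$aa_start[i] - 1L) + 1L
      nt_hi <- 3L * dom$aa_end[i]
      ex_rows <- coding[coding$exon >= dom$exon_start[i] &
                          coding$exon <= dom$exon_end[i], , drop = FALSE]
      if (nrow(ex_rows) == 0L) {
        note("domains", dom$name[i], "stated exon range contains no coding exon")
      } else if (nt_lo < min(ex_rows$cds_start) || nt_hi > max(ex_rows$cds_end)) {
        note("domains", dom$name[i],
             sprintf("aa interval (CDS %d-%d) falls outside stated exons %d-%d",
                     nt_lo, nt_hi, dom$exon_start[i], dom$exon_end[i]))
      }
    }
  }

  reg <- ref$regions
  if (nrow(reg) > 0L && nrow(coding) > 0L) {
    covered <- integer(0)
    for (i in seq_len(nrow(reg))) {
      covered <- c(covered, seq.int(reg$exon_start[i], reg$exon_end[i]))
    }
    dup <- intersect(unique(covered[duplicated(covered)]), coding$exon)
    for (e in dup) note("regions", e, "coding exon assigned to more than one region")
    missing <- setdiff(coding$exon, covered)
    for (e in missing) note("regions", e, "coding exon not covered by any region")
  }

  if (length(problems) == 0L) {
    data.frame(component = character(0), item = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, problems)
  }
}

#' @export
print.tsc_reference <- function(x, ...) {
  cat(sprintf("<tsc_reference> %s (%s): CDS %d nt, %d aa, %d domains, %d regions\n",
              x$gene, x$transcript_id, x$cds_length, x$protein_length,
              nrow(x$domains), nrow(x$regions)))
  invisible(x)
}

coding_exons <- function(ref) {
  ex <- ref$exons
  ex <- ex[ex$coding %in% TRUE, , drop = FALSE]
  ex[order(ex$exon), , drop = FALSE]
}
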
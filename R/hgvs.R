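# HGVS coding-DNA (c.) parsing. Scope: substitution, del, dup, ins, delins,
# with a single intronic offset on substitutions (c.N+K / c.N-K). Inversions,
# conversions, extensions and allele syntax are deliberately out of scope and
# raise an unsupported-form error distinct from a malformed-syntax error.

tscgp_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(class = c(class, "tscgp_error", "error", "condition"),
                 list(message = message, call = call)))
}

#' Parse coding-DNA HGVS descriptions
#'
#' Vectorised parser for `c.`-notation variant descriptions against a TSC
#' gene's coding sequence. Input is normalised for whitespace and letter case
#' before parsing, positions are validated against the transcript's CDS
#' length, and the result round-trips: `parse_hgvs_c(format_hgvs_c(pv), gene)`
#' equals `pv` for every supported form.
#'
#' @param x Character vector of HGVS `c.` descriptions (e.g. `"c.737G>A"`,
#'   `"c.1_3del"`, `"c.5068+1G>T"`, `"c.100_101insAG"`, `"c.10_12delinsG"`).
#' @param gene `"TSC1"` or `"TSC2"`; fixes the CDS length used for range
#'   checks.
#' @param ref Optional `tsc_reference`; defaults to the packaged tables.
#' @return A data frame (one row per input) with columns `gene`, `raw`,
#'   `kind` (`substitution`, `deletion`, `duplication`, `insertion`,
#'   `delins`), `cds_start`, `cds_end`, `intron_offset` (NA when absent),
#'   `ref_allele`, `alt_allele`, `length_change`, `protein_note`.
#' @section Errors: malformed syntax signals `tscgp_parse_error`, a position
#'   beyond the CDS signals `tscgp_range_error`, and recognised-but-excluded
#'   forms (e.g. inversions) signal `tscgp_unsupported_form`.
#' @export
#' @examples
#' parse_hgvs_c(c("c.737G>A", "c.1_3del", "c.5068+1G>T"), "TSC2")
parse_hgvs_c <- function(x, gene, ref = load_reference(gene)) {
  out <- parse_hgvs_c_quiet(x, gene, ref)
  bad <- which(!is.na(out$error))
  if (length(bad) > 0L) {
    i <- bad[1L]
    tscgp_error(out$error_class[i],
                sprintf("%s (input %d: \"%s\")", out$error[i], i, x[i]))
  }
  out$error <- NULL
  out$error_class <- NULL
  out
}

# Non-throwing core used by read_cohort(); adds error/error_class columns.
parse_hgvs_c_quiet <- function(x, gene, ref = load_reference(gene)) {
  gene <- match.arg(gene, c("TSC1", "TSC2"))
  n <- length(x)
  out <- data.frame(
    gene = rep(gene, n), raw = as.character(x),
    kind = NA_character_, cds_start = NA_integer_, cds_end = NA_integer_,
    intron_offset = NA_integer_, ref_allele = NA_character_,
    alt_allele = NA_character_, length_change = NA_integer_,
    protein_note = NA_character_, error = NA_character_,
    error_class = NA_character_, stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)

  u <- toupper(gsub("[[:space:]]+", "", as.character(x)))
  fail <- function(idx, class, msg) {
    sel <- idx & is.na(out$error)
    out$error[sel] <<- msg
    out$error_class[sel] <<- class
  }

  no_prefix <- !startsWith(u, "C.")
  fail(no_prefix, "tscgp_parse_error", "description must start with \"c.\"")
  body <- sub("^C\\.", "", u)

  unsupported <- grepl("INV|CON|EXT|\\[|\\]|\\(|\\)|=", body) |
    grepl("^\\*|^-", body) |                      # UTR-anchored positions
    grepl("[0-9][+-][0-9]+_", body) |             # offset on a range start
    grepl("_[0-9]+[+-][0-9]", body)               # offset on a range end
  fail(!no_prefix & unsupported, "tscgp_unsupported_form",
       "unsupported HGVS form (only sub/del/dup/ins/delins with a single intronic offset)")

  todo <- is.na(out$error)
  pats <- list(
    substitution = "^([0-9]+)([+-][0-9]+)?([ACGT])>([ACGT])$",
    delins       = "^([0-9]+)(_([0-9]+))?DELINS([ACGT]+)$",
    insertion    = "^([0-9]+)_([0-9]+)INS([ACGT]+)$",
    deletion     = "^([0-9]+)(_([0-9]+))?DEL([ACGT]+|[0-9]+)?$",
    duplication  = "^([0-9]+)(_([0-9]+))?DUP([ACGT]+|[0-9]+)?$"
  )
  grab <- function(pat, idx) {
    m <- regmatches(body[idx], regexec(pat, body[idx]))
    do.call(rbind, lapply(m, function(g) {
      if (length(g) == 0L) rep(NA_character_, 5L) else c(g, rep("", 5L - length(g)))[1:5]
    }))
  }

  for (kind in names(pats)) {
    idx <- which(todo & is.na(out$kind))
    if (length(idx) == 0L) break
    g <- grab(pats[[kind]], idx)
    hit <- !is.na(g[, 1L])
    if (!any(hit)) next
    rows <- idx[hit]
    g <- g[hit, , drop = FALSE]
    out$kind[rows] <- kind
    s <- as.integer(g[, 2L])
    out$cds_start[rows] <- s
    if (kind == "substitution") {
      out$cds_end[rows] <- s
      off <- g[, 3L]
      out$intron_offset[rows] <- ifelse(off == "", NA_integer_, as.integer(off))
      out$ref_allele[rows] <- g[, 4L]
      out$alt_allele[rows] <- g[, 5L]
      out$length_change[rows] <- 0L
    } else if (kind == "insertion") {
      e <- as.integer(g[, 3L])
      out$cds_end[rows] <- e
      out$alt_allele[rows] <- g[, 4L]
      out$length_change[rows] <- nchar(g[, 4L])
      bad <- e != s + 1L
      if (any(bad)) {
        sel <- rep(FALSE, n); sel[rows[bad]] <- TRUE
        fail(sel, "tscgp_parse_error",
             "insertion must be between two adjacent positions (c.N_(N+1)ins...)")
      }
    } else {
      e <- ifelse(g[, 4L] == "", s, as.integer(g[, 4L]))
      out$cds_end[rows] <- e
      span <- e - s + 1L
      if (kind == "deletion" || kind == "delins") {
        tail_tok <- g[, 5L]
        has_seq <- grepl("^[ACGT]+$", tail_tok) & kind == "deletion"
        out$ref_allele[rows[has_seq]] <- tail_tok[has_seq]
        stated_len <- suppressWarnings(
          ifelse(grepl("^[0-9]+$", tail_tok), as.integer(tail_tok),
                 ifelse(has_seq, nchar(tail_tok), NA_integer_)))
        bad_len <- !is.na(stated_len) & stated_len != span & kind == "deletion"
        if (any(bad_len)) {
          sel <- rep(FALSE, n); sel[rows[bad_len]] <- TRUE
          fail(sel, "tscgp_parse_error",
               "stated deleted length/sequence does not match the position span")
        }
      }
      if (kind == "deletion") {
        out$length_change[rows] <- -span
      } else if (kind == "duplication") {
        out$length_change[rows] <- span
      } else { # delins
        out$alt_allele[rows] <- g[, 5L]
        out$length_change[rows] <- nchar(g[, 5L]) - span
      }
    }
  }

  fail(is.na(out$error) & is.na(out$kind), "tscgp_parse_error",
       "malformed HGVS c. description")

  ok <- is.na(out$error)
  bad_order <- ok & out$cds_end < out$cds_start
  fail(bad_order, "tscgp_parse_error", "cds_start exceeds cds_end")
  ok <- is.na(out$error)
  out_of_range <- ok & (out$cds_start < 1L | out$cds_end > ref$cds_length)
  fail(out_of_range, "tscgp_range_error",
       sprintf("position outside CDS [1, %d]", ref$cds_length))
  out
}

#' Serialise parsed variants back to canonical HGVS strings
#'
#' @param pv Data frame as returned by [parse_hgvs_c()].
#' @return Character vector of canonical `c.` descriptions.
#' @export
format_hgvs_c <- function(pv) {
  off <- ifelse(is.na(pv$intron_offset), "",
                sprintf("%+d", pv$intron_offset))
  range_part <- ifelse(pv$cds_end > pv$cds_start,
                       paste0(pv$cds_start, "_", pv$cds_end),
                       as.character(pv$cds_start))
  ifelse(pv$kind == "substitution",
         paste0("c.", pv$cds_start, off, pv$ref_allele, ">", pv$alt_allele),
  ifelse(pv$kind == "deletion", paste0("c.", range_part, "del"),
  ifelse(pv$kind == "duplication", paste0("c.", range_part, "dup"),
  ifelse(pv$kind == "insertion",
         paste0("c.", pv$cds_start, "_", pv$cds_end, "ins", pv$alt_allele),
         paste0("c.", range_part, "delins", pv$alt_allele)))))
}

#' Codon arithmetic: CDS position to protein residue index
#'
#' Residue `i` occupies CDS nucleotides `3*(i-1)+1 .. 3*i`, so the residue of
#' CDS position `p` is `ceiling(p / 3)`.
#'
#' @param pos Integer vector of CDS positions (1-based).
#' @param cds_length Optional upper bound for range checking.
#' @return Integer vector of residue indices.
#' @export
#' @examples
#' cds_to_protein(737)  # residue 246
cds_to_protein <- function(pos, cds_length = NULL) {
  if (any(!is.finite(pos)) || any(pos < 1)) {
    tscgp_error("tscgp_range_error", "CDS position must be >= 1")
  }
  if (!is.null(cds_length) && any(pos > cds_length)) {
    tscgp_error("tscgp_range_error",
                sprintf("CDS position outside [1, %d]", cds_length))
  }
  as.integer(ceiling(pos / 3))
}
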
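#' Classification settings for the mutation-type taxonomy
#'
#' @param splice_window Intronic offsets with absolute value up to this bound
#'   are splice-site mutations (default 2: the canonical donor/acceptor
#'   dinucleotides). Larger offsets are splice-site only when the declared
#'   source label says so.
#' @param large_fragment_nt A deletion/duplication whose affected span is at
#'   least this many nucleotides, or which contains at least one entire exon,
#'   is a large-fragment (large genomic rearrangement) mutation. Default 50,
#'   the usual indel/LGR boundary.
#' @param strict When `TRUE`, a substitution with no declared protein
#'   consequence is an error instead of a low-confidence missense call.
#' @return A list of class `tscgp_class_config`.
#' @export
classification_config <- function(splice_window = 2L, large_fragment_nt = 50L,
                                  strict = FALSE) {
  stopifnot(splice_window >= 0, large_fragment_nt >= 1)
  structure(list(splice_window = as.integer(splice_window),
                 large_fragment_nt = as.integer(large_fragment_nt),
                 strict = isTRUE(strict)),
            class = "tscgp_class_config")
}

normalize_type_label <- function(x) {
  y <- tolower(gsub("[ -]", "_", trimws(x)))
  y[y %in% c("splice", "splicesite", "splice_site")] <- "splice_site"
  y[y %in% c("inframe", "in_frame")] <- "in_frame"
  y[y %in% c("largefragment", "large_fragment", "lgr")] <- "large_fragment"
  y[y %in% c("non_sense", "nonsense")] <- "nonsense"
  y
}

declares_stop <- function(p) {
  !is.na(p) & (grepl("Ter", p, fixed = TRUE) | grepl("\\*", p) |
                 grepl("[A-Za-z][0-9]+X\\)?$", p))
}

#' Classify parsed variants into the six-way mutation-type taxonomy
#'
#' Deterministic classification into `missense`, `nonsense`, `frameshift`,
#' `splice_site`, `in_frame` or `large_fragment`. Precedence: a declared
#' source label naming one of the six types wins (this resolves variants that
#' are simultaneously splice-affecting and missense to the source's single
#' tally); then an intronic offset within the splice window gives
#' `splice_site`; then a deletion/duplication meeting the large-fragment rule
#' gives `large_fragment`; remaining indels are `frameshift` or `in_frame` by
#' `length_change %% 3`; substitutions are `nonsense` when the declared
#' protein consequence contains a stop (`Ter`/`*`/`X`), otherwise `missense`.
#' A substitution with no declared consequence is classified `missense` with
#' its entry in the `low_confidence` attribute set (never a silent guess), or
#' is an error in strict mode. Deep-intronic substitutions beyond the splice
#' window with no declared label are likewise low-confidence `splice_site`
#' calls.
#'
#' @param variants Data frame from [parse_hgvs_c()].
#' @param declared Optional character vector (recycled if length 1): either a
#'   protein-level HGVS note (`"p.(Arg246Lys)"`, `"p.Gln123Ter"`) or a source
#'   type label (one of the six tokens).
#' @param ref `tsc_reference` used for the entire-exon large-fragment rule;
#'   defaults to the packaged tables for `variants$gene`.
#' @param config A [classification_config()].
#' @return Character vector of types with attribute `low_confidence`
#'   (logical vector).
#' @export
#' @examples
#' v <- parse_hgvs_c("c.737G>A", "TSC1")
#' classify_mutation_type(v, "p.(Arg246Lys)")
classify_mutation_type <- function(variants, declared = NULL,
                                   ref = load_reference(variants$gene[1L]),
                                   config = classification_config()) {
  n <- nrow(variants)
  type <- rep(NA_character_, n)
  low_conf <- rep(FALSE, n)
  if (n == 0L) return(structure(character(0), low_confidence = logical(0)))
  if (is.null(declared)) declared <- rep(NA_character_, n)
  if (length(declared) == 1L) declared <- rep(declared, n)
  stopifnot(length(declared) == n)

  lab <- normalize_type_label(declared)
  from_label <- !is.na(lab) & lab %in% MUTATION_TYPES
  type[from_label] <- lab[from_label]

  todo <- is.na(type)
  splice <- todo & !is.na(variants$intron_offset) &
    abs(variants$intron_offset) <= config$splice_window
  type[splice] <- "splice_site"

  deep_intronic <- is.na(type) & !is.na(variants$intron_offset)
  type[deep_intronic] <- "splice_site"
  low_conf[deep_intronic] <- TRUE

  span <- variants$cds_end - variants$cds_start + 1L
  cex <- coding_exons(ref)
  contains_exon <- vapply(seq_len(n), function(i) {
    any(cex$cds_start >= variants$cds_start[i] & cex$cds_end <= variants$cds_end[i])
  }, logical(1))
  large <- is.na(type) & variants$kind %in% c("deletion", "duplication") &
    (span >= config$large_fragment_nt | contains_exon)
  type[large] <- "large_fragment"

  indel <- is.na(type) &
    variants$kind %in% c("deletion", "duplication", "insertion", "delins")
  type[indel & variants$length_change %% 3L != 0L] <- "frameshift"
  type[indel & variants$length_change %% 3L == 0L] <- "in_frame"

  sub <- is.na(type) & variants$kind == "substitution"
  has_p <- sub & !is.na(declared) & grepl("p\\.", declared)
  type[has_p & declares_stop(declared)] <- "nonsense"
  type[has_p & !declares_stop(declared)] <- "missense"
  unresolved <- sub & !has_p
  if (any(unresolved)) {
    if (config$strict) {
      tscgp_error("tscgp_unresolvable_class",
                  sprintf("substitution with no declared protein consequence (e.g. \"%s\")",
                          variants$raw[which(unresolved)[1L]]))
    }
    type[unresolved] <- "missense"
    low_conf[unresolved] <- TRUE
  }
  structure(type, low_confidence = low_conf)
}

#' Protein-truncating (PT) versus non-truncating (NT) class
#'
#' Total, exclusive map over the six mutation types: frameshift, splice-site,
#' nonsense and large-fragment mutations truncate the protein (PT); missense
#' and in-frame mutations do not (NT).
#'
#' @param type Character vector of mutation types.
#' @return Character vector of `"PT"` / `"NT"`.
#' @export
#' @examples
#' classify_truncation(c("nonsense", "in_frame"))
classify_truncation <- function(type) {
  type <- as.character(type)
  bad <- !(type %in% MUTATION_TYPES)
  if (any(bad)) {
    stop("unknown mutation type: ", paste(unique(type[bad]), collapse = ", "),
         call. = FALSE)
  }
  ifelse(type %in% PT_TYPES, "PT", "NT")
}
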
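# Cohort ingest and the full association analysis. The cohort schema is one
# row per patient: patient_id, gene, transcript, hgvs_c, hgvs_p, sex, raml,
# source. One variant per record: rows carrying several c. descriptions are
# rejected at ingest (cohorts built from curated literature exclude patients
# with two or more variants rather than adjudicating between them).

COHORT_COLUMNS <- c("patient_id", "gene", "transcript", "hgvs_c", "hgvs_p",
                    "sex", "raml", "source")

normalize_sex <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y[y %in% c("f", "female")] <- "female"
  y[y %in% c("m", "male")] <- "male"
  y[is.na(y) | y %in% c("", "na", "u", "unk", "unknown")] <- "unknown"
  y
}

parse_logical_col <- function(x) {
  y <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[y %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[y %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Read and validate a cohort table
#'
#' Reads a CSV or TSV cohort file (delimiter chosen from the file
#' extension), normalises the `sex` and `raml` columns, and screens every
#' row: unknown gene, unparseable or multi-variant HGVS, and missing RAML
#' status are rejected with itemised reasons rather than failing the load.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file with header columns
#'   `patient_id`, `gene`, `hgvs_c`, `sex`, `raml` (mandatory) and
#'   `transcript`, `hgvs_p`, `source` (optional).
#' @return A list of class `tsc_cohort`: `records` (clean rows) and
#'   `rejected` (data frame with a `reason` column, zero rows when all pass).
#' @section Errors: a missing mandatory column or a duplicated `patient_id`
#'   is an error (the file itself is malformed, not individual rows).
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (nrow(df) == 0L) {
    warning("empty cohort file: ", path, call. = FALSE)
  }
  mandatory <- c("patient_id", "gene", "hgvs_c", "sex", "raml")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(COHORT_COLUMNS, names(df))) {
    df[[col]] <- rep(NA_character_, nrow(df))
  }
  df <- df[, COHORT_COLUMNS, drop = FALSE]
  dup <- duplicated(df$patient_id)
  if (any(dup)) {
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[dup]), collapse = ", "), call. = FALSE)
  }
  df$sex <- normalize_sex(df$sex)
  df$raml <- parse_logical_col(df$raml)
  df$gene <- toupper(trimws(df$gene))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(sel, why) reason[sel & is.na(reason)] <<- why
  flag(!(df$gene %in% c("TSC1", "TSC2")), "unknown gene (must be TSC1 or TSC2)")
  multi <- grepl("[;,]", df$hgvs_c) |
    lengths(gregexpr("c\\.", df$hgvs_c, ignore.case = TRUE)) > 1L
  flag(multi, "two or more variants in one record")
  flag(is.na(df$raml), "missing RAML status")
  for (g in c("TSC1", "TSC2")) {
    i <- which(is.na(reason) & df$gene == g)
    if (length(i) == 0L) next
    pv <- parse_hgvs_c_quiet(df$hgvs_c[i], g)
    bad <- !is.na(pv$error)
    reason[i[bad]] <- paste0("HGVS: ", pv$error[bad])
  }
  rejected <- cbind(df[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  rownames(rejected) <- NULL
  records <- df[is.na(reason), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, rejected = rejected),
            class = "tsc_cohort")
}

#' @export
print.tsc_cohort <- function(x, ...) {
  cat(sprintf("<tsc_cohort> %d records (%d rejected)\n",
              nrow(x$records), nrow(x$rejected)))
  invisible(x)
}

#' Cross-tabulate an exposure against RAML status
#'
#' @param cohort Annotated (or raw) cohort data frame with a logical `raml`
#'   column.
#' @param exposure Either a logical vector aligned with `cohort` rows or a
#'   one-argument predicate function applied to the cohort.
#' @return A [table2x2()] whose cells sum to `nrow(cohort)`; a zero exposure
#'   or outcome margin is flagged via the attribute `degenerate`.
#' @export
build_table <- function(cohort, exposure) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  e <- if (is.function(exposure)) exposure(cohort) else exposure
  stopifnot(is.logical(e), length(e) == nrow(cohort))
  o <- cohort$raml
  t <- table2x2(sum(e & o), sum(e & !o), sum(!e & o), sum(!e & !o))
  m <- as.matrix(t)
  attr(t, "degenerate") <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  t
}

empty_comparison_row <- function() {
  data.frame(
    analysis = character(0), gene = character(0), label = character(0),
    a = integer(0), b = integer(0), c = integer(0), d = integer(0),
    n = integer(0), method = character(0), marker = character(0),
    statistic = numeric(0), p_value = numeric(0), or = numeric(0),
    ci_low = numeric(0), ci_high = numeric(0), or_defined = logical(0),
    logistic_or = numeric(0), logistic_ci_low = numeric(0),
    logistic_ci_high = numeric(0), logistic_p = numeric(0),
    stringsAsFactors = FALSE
  )
}

comparison_row <- function(analysis, gene, label, t, logistic = TRUE,
                           alpha = 0.05) {
  row <- list(analysis = analysis, gene = gene, label = label,
              a = t$a, b = t$b, c = t$c, d = t$d, n = attr(t, "n"))
  if (isTRUE(attr(t, "degenerate"))) {
    row <- c(row, list(method = "none", marker = "-", statistic = NA_real_,
                       p_value = NA_real_))
  } else {
    res <- test_2x2(t)
    row <- c(row, list(method = res$method, marker = res$marker,
                       statistic = res$statistic, p_value = res$p_value))
  }
  or <- odds_ratio_woolf(t, alpha = alpha)
  row <- c(row, list(or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
                     or_defined = or$defined))
  if (logistic && or$defined) {
    lo <- logistic_crude_or(t, alpha = alpha)
    row <- c(row, list(logistic_or = lo$or, logistic_ci_low = lo$ci_low,
                       logistic_ci_high = lo$ci_high, logistic_p = lo$p_value))
  } else {
    row <- c(row, list(logistic_or = NA_real_, logistic_ci_low = NA_real_,
                       logistic_ci_high = NA_real_, logistic_p = NA_real_))
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Run the full genotype-phenotype association analysis
#'
#' Annotates the cohort and builds every exposure-by-RAML comparison of the
#' standard analysis plan: (1) gene (TSC1 vs TSC2); (2) sex (records of
#' unknown sex excluded from this comparison only); (3) per gene, each
#' observed mutation type versus all other types, plus PT versus NT; (4) per
#' gene, each functional domain versus all other (non-large-fragment)
#' variants, plus an "Others" row for variants hitting no listed domain —
#' large-fragment mutations are excluded from the domain and region analyses
#' because their lesion spans many domains at once; (5) each region versus
#' the rest, on the same large-fragment-excluded set. Domain rows are
#' separate category-vs-rest comparisons, not a partition: a variant hitting
#' two domains is counted in both rows. Every comparison carries the
#' rule-selected test ([select_test()]), the Woolf odds ratio, and (by
#' default) the crude logistic odds ratio with its Wald p-value.
#'
#' @param cohort Data frame of validated records (e.g.
#'   `read_cohort(path)$records` or [paper_cohort()]).
#' @param logistic Also fit the crude logistic OR for each non-degenerate
#'   comparison.
#' @param bh Add a Benjamini-Hochberg adjusted p-value column `p_bh`
#'   (annotation only; the primary p-values are unadjusted).
#' @param alpha CI error rate.
#' @param config,region_rule,propagate_domains,reference_dir Passed to
#'   [annotate_cohort()].
#' @return A list of class `tscgp_report`: `comparisons` (one data frame row
#'   per comparison), `metadata` (cohort sizes and itemised exclusions) and
#'   `annotated` (the annotated cohort).
#' @export
#' @examples
#' rep <- analyze(paper_cohort())
#' subset(rep$comparisons, label == "TAD1")
analyze <- function(cohort, logistic = TRUE, bh = FALSE, alpha = 0.05,
                    config = classification_config(),
                    region_rule = "five_prime", propagate_domains = FALSE,
                    reference_dir = NULL) {
  ann <- annotate_cohort(cohort, config = config, region_rule = region_rule,
                         propagate_domains = propagate_domains,
                         reference_dir = reference_dir)
  stopifnot(is.logical(ann$raml), !anyNA(ann$raml))
  ann$sex <- normalize_sex(ann$sex)
  rows <- list()
  notes <- character(0)

  genes <- intersect(c("TSC1", "TSC2"), unique(ann$gene))
  if (length(genes) == 2L) {
    rows[[length(rows) + 1L]] <- comparison_row(
      "gene", NA_character_, "TSC1 vs TSC2",
      build_table(ann, ann$gene == "TSC1"), logistic, alpha)
  } else {
    notes <- c(notes, "gene comparison omitted: single-gene cohort")
  }

  known_sex <- ann[ann$sex != "unknown", , drop = FALSE]
  if (nrow(known_sex) > 0L && length(unique(known_sex$sex)) == 2L) {
    rows[[length(rows) + 1L]] <- comparison_row(
      "sex", NA_character_, "female vs male",
      build_table(known_sex, known_sex$sex == "female"), logistic, alpha)
  } else {
    notes <- c(notes, "sex comparison omitted: fewer than two known sexes")
  }

  for (g in genes) {
    sub <- ann[ann$gene == g, , drop = FALSE]
    ref <- load_reference(g, dir = reference_dir)

    for (ty in intersect(MUTATION_TYPES, unique(sub$mutation_type))) {
      rows[[length(rows) + 1L]] <- comparison_row(
        "type", g, ty, build_table(sub, sub$mutation_type == ty),
        logistic, alpha)
    }
    rows[[length(rows) + 1L]] <- comparison_row(
      "truncation", g, "PT vs NT",
      build_table(sub, sub$truncation == "PT"), logistic, alpha)

    no_lf <- sub[sub$mutation_type != "large_fragment", , drop = FALSE]
    if (nrow(no_lf) == 0L) next
    dom_labels <- unique(ref$domains$name)
    if (all(c("TAD2", "CaBD") %in% dom_labels)) {
      dom_labels <- c(setdiff(dom_labels, c("TAD2", "CaBD")), "TAD2+CaBD")
    }
    for (dm in dom_labels) {
      rows[[length(rows) + 1L]] <- comparison_row(
        "domain", g, dm, build_table(no_lf, has_domain(no_lf$domains, dm)),
        logistic, alpha)
    }
    rows[[length(rows) + 1L]] <- comparison_row(
      "domain", g, "Others", build_table(no_lf, no_lf$domains == ""),
      logistic, alpha)
    for (rg in ref$regions$name) {
      rows[[length(rows) + 1L]] <- comparison_row(
        "region", g, rg, build_table(no_lf, no_lf$region == rg),
        logistic, alpha)
    }
  }

  comparisons <- if (length(rows) == 0L) empty_comparison_row() else
    do.call(rbind, rows)
  if (bh) comparisons$p_bh <- p.adjust(comparisons$p_value, method = "BH")

  lf_excluded <- vapply(genes, function(g) {
    sum(ann$gene == g & ann$mutation_type == "large_fragment")
  }, integer(1))
  report <- structure(
    list(comparisons = comparisons,
         metadata = list(
           n_total = nrow(ann),
           n_by_gene = as.list(table(ann$gene)),
           n_raml = sum(ann$raml),
           n_unknown_sex = sum(ann$sex == "unknown"),
           large_fragments_excluded_from_domains =
             as.list(setNames(as.integer(lf_excluded), genes)),
           alpha = alpha, logistic = logistic,
           notes = notes,
           package_version = as.character(packageVersion("tscgp"))),
         annotated = ann),
    class = "tscgp_report")
  report
}

#' @export
print.tscgp_report <- function(x, ...) {
  cat(sprintf("<tscgp_report> %d patients, %d comparisons\n",
              x$metadata$n_total, nrow(x$comparisons)))
  invisible(x)
}

format_report_table <- function(cmp) {
  pct <- function(k, total) ifelse(total == 0, "-",
                                   sprintf("%d (%.2f%%)", k, 100 * k / total))
  data.frame(
    analysis = cmp$analysis,
    gene = ifelse(is.na(cmp$gene), "", cmp$gene),
    category = cmp$label,
    raml = pct(cmp$a, cmp$a + cmp$c),
    non_raml = pct(cmp$b, cmp$b + cmp$d),
    p = ifelse(is.na(cmp$p_value), "-",
               paste0(sprintf("%.3f", cmp$p_value), cmp$marker)),
    or = ifelse(cmp$or_defined, sprintf("%.3f", cmp$or), "-"),
    ci = ifelse(cmp$or_defined,
                sprintf("(%.3f-%.3f)", cmp$ci_low, cmp$ci_high), "-"),
    logistic_or = ifelse(is.na(cmp$logistic_or), "-",
                         sprintf("%.3f (%.3f-%.3f), p=%.3f", cmp$logistic_or,
                                 cmp$logistic_ci_low, cmp$logistic_ci_high,
                                 cmp$logistic_p)),
    stringsAsFactors = FALSE
  )
}

#' Serialise an analysis report
#'
#' The TSV mirrors the layout of published genotype-phenotype tables —
#' category, RAML n (percent of the RAML column), non-RAML n (percent), p
#' with the method marker (`&` = continuity-corrected, `F` = Fisher), OR and
#' CI — with p-values and ORs rounded to 3 decimals and percentages to 2.
#' The JSON twin keeps full precision and round-trips through
#' [read_report()]. Output is deterministic: the same report always
#' serialises to the same bytes.
#'
#' @param report A `tscgp_report` from [analyze()].
#' @param path Output file; when `NULL` the serialised text is returned.
#' @param format `"tsv"` or `"json"`.
#' @return The serialised text, invisibly when written to `path`.
#' @export
write_report <- function(report, path = NULL, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- format_report_table(report$comparisons)
    lines <- c(paste(names(tab), collapse = "\t"),
               do.call(paste, c(unname(as.list(tab)), sep = "\t")))
    text <- paste0(paste(lines, collapse = "\n"), "\n")
  } else {
    payload <- list(comparisons = report$comparisons,
                    metadata = report$metadata)
    text <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                          digits = NA, na = "null",
                                          pretty = TRUE))
  }
  if (is.null(path)) return(text)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(text, con, sep = "")
  invisible(text)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path JSON file path.
#' @return A `tscgp_report` (without the `annotated` cohort, which is not
#'   serialised).
#' @export
read_report <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cmp <- as.data.frame(payload$comparisons, stringsAsFactors = FALSE)
  structure(list(comparisons = cmp, metadata = payload$metadata),
            class = "tscgp_report")
}
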
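write_cohort_file <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  write.table(df, path, sep = if (ext == "csv") "," else "\t",
              row.names = FALSE, quote = FALSE)
  path
}

test_that("read_cohort validates rows and itemises rejections", {
  df <- data.frame(
    patient_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    gene = c("TSC1", "TSC2", "TSC9", "TSC1", "TSC2", "tsc2"),
    hgvs_c = c("c.737G>A", "c.3500G>A", "c.1A>G", "c.1A>G;c.2A>G",
               "c.99999G>A", "c.100del"),
    sex = c("F", "male", "", "female", "M", NA),
    raml = c("yes", "0", "1", "TRUE", "no", "1"),
    stringsAsFactors = FALSE
  )
  coh <- read_cohort(write_cohort_file(df))
  expect_s3_class(coh, "tsc_cohort")
  expect_equal(coh$records$patient_id, c("p1", "p2", "p6"))
  expect_equal(coh$records$sex, c("female", "male", "unknown"))
  expect_equal(coh$records$raml, c(TRUE, FALSE, TRUE))
  expect_equal(nrow(coh$rejected), 3)
  expect_match(coh$rejected$reason[coh$rejected$patient_id == "p3"],
               "unknown gene")
  expect_match(coh$rejected$reason[coh$rejected$patient_id == "p4"],
               "two or more variants")
  expect_match(coh$rejected$reason[coh$rejected$patient_id == "p5"],
               "outside CDS")

  # TSV route reads identically
  coh2 <- read_cohort(write_cohort_file(df, "tsv"))
  expect_equal(coh2$records, coh$records)

  expect_error(read_cohort(write_cohort_file(df[, -1])), "mandatory column")
  expect_error(
    read_cohort(write_cohort_file(rbind(df[1, ], df[1, ]))),
    "duplicate patient_id")
  empty <- df[0, ]
  expect_warning(coh3 <- read_cohort(write_cohort_file(empty)), "empty")
  expect_equal(nrow(coh3$records), 0)
})

test_that("build_table follows the orientation contract and flags degeneracy", {
  coh <- annotate_cohort(paper_cohort())
  t <- build_table(coh, coh$gene == "TSC1")
  expect_equal(c(t$a, t$b, t$c, t$d), c(22, 32, 104, 103))
  known <- coh[coh$sex != "unknown", ]
  t <- build_table(known, known$sex == "female")
  expect_equal(c(t$a, t$b, t$c, t$d), c(47, 38, 21, 42))
  t <- build_table(coh, rep(TRUE, nrow(coh)))
  expect_true(attr(t, "degenerate"))
  expect_error(build_table(coh[0, ], logical(0)), "empty cohort")
})

test_that("the fixture cohort reproduces the published category counts", {
  coh <- paper_cohort()
  expect_equal(nrow(coh), 261)
  expect_equal(as.vector(table(coh$gene)), c(54, 207))
  ann <- annotate_cohort(coh)

  counts <- function(g) table(factor(ann$mutation_type[ann$gene == g],
                                     levels = c("missense", "nonsense",
                                                "frameshift", "splice_site",
                                                "in_frame", "large_fragment")),
                              ann$raml[ann$gene == g])
  tsc1 <- counts("TSC1")
  expect_equal(unname(tsc1[, "TRUE"]), c(11, 6, 4, 0, 0, 1))
  expect_equal(unname(tsc1[, "FALSE"]), c(2, 12, 15, 0, 0, 3))
  tsc2 <- counts("TSC2")
  expect_equal(unname(tsc2[, "TRUE"]), c(25, 21, 36, 10, 4, 8))
  expect_equal(unname(tsc2[, "FALSE"]), c(34, 19, 27, 14, 6, 3))

  expect_equal(as.vector(table(coh$sex, coh$raml)),
               c(38, 42, 55, 47, 21, 58))
})

test_that("analyze builds every planned comparison with conserved counts", {
  rep <- analyze(paper_cohort())
  cmp <- rep$comparisons
  expect_setequal(unique(cmp$analysis),
                  c("gene", "sex", "type", "truncation", "domain", "region"))
  # count conservation: cohort minus itemised exclusions
  expect_true(all(cmp$n[cmp$analysis == "gene"] == 261))
  expect_true(all(cmp$n[cmp$analysis == "sex"] == 261 - 113))
  expect_true(all(cmp$n[cmp$analysis %in% c("type", "truncation") &
                          cmp$gene == "TSC1"] == 54))
  expect_true(all(cmp$n[cmp$analysis %in% c("domain", "region") &
                          cmp$gene == "TSC2"] == 207 - 11))
  expect_true(all(cmp$n[cmp$analysis %in% c("domain", "region") &
                          cmp$gene == "TSC1"] == 54 - 4))
  # margins consistent with the annotated cohort for every row
  with(cmp, expect_true(all(a + b + c + d == n)))
  # the empty LZD row is reported with the undefined flag, like a dash
  lzd <- report_row(rep, "LZD", "TSC2")
  expect_equal(lzd$method, "none")
  expect_false(lzd$or_defined)
})

test_that("single-gene cohorts omit the gene comparison with a note", {
  coh <- paper_cohort()
  rep <- analyze(coh[coh$gene == "TSC2", ])
  expect_false("gene" %in% rep$comparisons$analysis)
  expect_match(rep$metadata$notes, "single-gene", all = FALSE)
})

test_that("reports serialise deterministically, round-trip, and mark methods", {
  rep <- analyze(paper_cohort())
  tsv1 <- write_report(rep, format = "tsv")
  tsv2 <- write_report(analyze(paper_cohort()), format = "tsv")
  expect_identical(tsv1, tsv2)  # byte-identical: no hidden randomness

  lines <- strsplit(tsv1, "\n")[[1]]
  header <- strsplit(lines[1], "\t")[[1]]
  expect_equal(header[1:5], c("analysis", "gene", "category", "raml",
                              "non_raml"))
  # TSC1 type analysis rows: 4 observed types + PT vs NT
  expect_equal(sum(grepl("^type\tTSC1", lines)), 4)
  tab <- read.delim(text = tsv1, stringsAsFactors = FALSE)
  # continuity-corrected rows are marked '&' exactly when Yates was selected
  expect_equal(grepl("&", tab$p),
               rep$comparisons$method == "chi_square_yates")
  # percentages recompute exactly from the cells
  pcts <- as.numeric(sub(".*\\((.*)%\\)", "\\1", tab$raml))
  expect_equal(pcts, round(100 * rep$comparisons$a /
                             (rep$comparisons$a + rep$comparisons$c), 2))

  json_path <- tempfile(fileext = ".json")
  write_report(rep, json_path, format = "json")
  back <- read_report(json_path)
  expect_equal(back$comparisons, rep$comparisons, tolerance = 1e-12)

  # Benjamini-Hochberg annotation is optional and leaves primary p untouched
  rep_bh <- analyze(paper_cohort(), bh = TRUE)
  expect_true("p_bh" %in% names(rep_bh$comparisons))
  expect_equal(rep_bh$comparisons$p_value, rep$comparisons$p_value)
  expect_true(all(rep_bh$comparisons$p_bh >= rep_bh$comparisons$p_value,
                  na.rm = TRUE))
})
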
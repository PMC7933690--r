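test_that("cds_to_exon agrees with a linear-scan oracle and handles bounds", {
  expect_equal(cds_to_exon(1, ref_tsc1), 3)  # first coding exon of TSC1
  expect_equal(cds_to_exon(ref_tsc1$cds_length, ref_tsc1), 23)
  expect_equal(cds_to_exon(1, ref_tsc2), 1)
  expect_equal(cds_to_exon(ref_tsc2$cds_length, ref_tsc2), 41)
  expect_equal(cds_to_exon(3489, ref_tsc2), 29)
  expect_error(cds_to_exon(0, ref_tsc2), class = "tscgp_range_error")
  expect_error(cds_to_exon(5425, ref_tsc2), class = "tscgp_range_error")

  linear_scan <- function(pos, ref) {
    cex <- ref$exons[ref$exons$coding %in% TRUE, ]
    cex$exon[pos >= cex$cds_start & pos <= cex$cds_end]
  }
  set.seed(31)
  for (ref in list(ref_tsc1, ref_tsc2)) {
    pos <- sample.int(ref$cds_length, 300)
    expect_equal(cds_to_exon(pos, ref),
                 vapply(pos, linear_scan, numeric(1), ref = ref))
  }
})

test_that("domain assignment matches published examples and the merged TAD2+CaBD group", {
  hit1 <- function(res, ref) {
    ex <- cds_to_exon(3 * res, ref)
    assign_domains(res, res, ex, ex, ref)[[1]]
  }
  expect_equal(hit1(1200, ref_tsc2), "TAD1")
  expect_equal(hit1(1742, ref_tsc2), "TAD2+CaBD")  # overlap residues 1740-1744
  expect_equal(hit1(1690, ref_tsc2), "TAD2+CaBD")
  expect_equal(hit1(1755, ref_tsc2), "TAD2+CaBD")
  expect_equal(hit1(500, ref_tsc1), character(0))  # between TMD and CCD, exon 7
  expect_equal(hit1(135, ref_tsc1), "TMD")
  # TID hits through the exon route (no aa interval)
  expect_equal(hit1(250, ref_tsc1), "TID")  # residue 250 -> CDS 750, exon 9
})

test_that("domain assignment agrees with the brute-force residue oracle", {
  set.seed(32)
  for (ref in list(ref_tsc1, ref_tsc2)) {
    start <- sample.int(ref$cds_length - 200L, 200)
    end <- pmin(start + sample.int(150L, 200, replace = TRUE) - 1L,
                ref$cds_length)
    rs <- cds_to_protein(start)
    re <- cds_to_protein(end)
    es <- cds_to_exon(start, ref)
    ee <- cds_to_exon(end, ref)
    got <- assign_domains(rs, re, es, ee, ref)
    for (i in seq_along(start)) {
      expect_setequal(got[[i]], domain_oracle(rs[i], re[i], es[i], ee[i], ref))
    }
  }
})

test_that("downstream propagation is off by default and available as an option", {
  # nonsense at residue 100 of TSC2: position-only membership is empty
  ex <- cds_to_exon(300, ref_tsc2)
  expect_equal(assign_domains(100, 100, ex, ex, ref_tsc2)[[1]], character(0))
  prop <- assign_domains(100, 100, ex, ex, ref_tsc2, propagate = TRUE)[[1]]
  expect_setequal(prop, c("CCD1", "CCD2", "TAD1", "GAPD", "TAD2+CaBD"))
})

test_that("region assignment: published exon examples and the 5'-rule for spans", {
  r <- function(e, ref) assign_region(e, e, ref)$region
  expect_equal(r(30, ref_tsc2), "middle")  # TAD1 exons are middle-region
  expect_equal(r(35, ref_tsc2), "GAP")
  expect_equal(r(22, ref_tsc2), "HID-TID")
  expect_equal(r(6, ref_tsc1), "N-terminal")
  expect_equal(r(15, ref_tsc1), "N-terminal")  # boundary exon on the N side
  expect_equal(r(16, ref_tsc1), "C-terminal")
  # a large fragment spanning the HID-TID/middle boundary
  span <- assign_region(22, 24, ref_tsc2)
  expect_equal(span$region, "HID-TID")
  expect_true(span$region_ambiguous)
  expect_equal(assign_region(22, 24, ref_tsc2, rule = "three_prime")$region,
               "middle")
})

test_that("every coding variant gets exactly one region", {
  set.seed(33)
  for (ref in list(ref_tsc1, ref_tsc2)) {
    pos <- sample.int(ref$cds_length, 300)
    ex <- cds_to_exon(pos, ref)
    reg <- assign_region(ex, ex, ref)
    expect_false(any(is.na(reg$region)))
    expect_true(all(reg$region %in% ref$regions$name))
    expect_false(any(reg$region_ambiguous))
  }
})

test_that("annotate_cohort runs the full stack and preserves row order", {
  records <- data.frame(
    patient_id = c("a", "b", "c", "d"),
    gene = c("TSC2", "TSC1", "TSC2", "TSC1"),
    hgvs_c = c("c.3500G>A", "c.737G>A", "c.3611+1G>A", "c.2400_2401del"),
    hgvs_p = c("p.(Gly1167Asp)", "p.(Arg246Lys)", NA, NA),
    sex = c("female", "male", "unknown", "female"),
    raml = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  ann <- annotate_cohort(records)
  expect_equal(ann$patient_id, records$patient_id)
  expect_equal(ann$mutation_type,
               c("missense", "missense", "splice_site", "frameshift"))
  expect_equal(ann$truncation, c("NT", "NT", "PT", "PT"))
  expect_equal(ann$exon_start, c(29, 8, 29, 19))
  expect_equal(ann$domains, c("TAD1", "TID", "TAD1", "CCD"))
  expect_equal(ann$region, c("middle", "N-terminal", "middle", "C-terminal"))
  expect_equal(ann$residue_start, c(1167, 246, 1204, 800))
  expect_error(annotate_cohort(data.frame(gene = "TSC3", hgvs_c = "c.1A>G")),
               "unknown gene")
})
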
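Package: tscgp
Title: Genotype-Phenotype Association Analysis for Tuberous Sclerosis
    Complex and Renal Angiomyolipoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genotype-phenotype correlation studies of tuberous
    sclerosis complex (TSC). Parses coding-DNA HGVS variant descriptions for
    TSC1 and TSC2, classifies variants into the standard mutation-type
    taxonomy (missense, nonsense, frameshift, splice-site, in-frame,
    large-fragment) and protein-truncating versus non-truncating classes,
    maps variants onto hamartin and tuberin functional-domain and region
    coordinates, and performs 2x2 contingency association analysis against
    renal angiomyolipoma status with an expected-count based test-selection
    rule (chi-square, continuity-corrected chi-square, Fisher's exact test),
    Woolf odds-ratio confidence intervals, and crude binary-logistic odds
    ratios. Includes a deterministic reference-cohort fixture built from
    published category counts and a seeded synthetic-cohort generator for
    parameter-recovery and type-I-error experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
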
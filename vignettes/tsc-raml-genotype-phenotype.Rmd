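---
title: "Genotype-phenotype association for TSC renal angiomyolipoma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-phenotype association for TSC renal angiomyolipoma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscgp)
```

## The problem

Tuberous sclerosis complex (TSC) is an autosomal dominant hamartoma syndrome
caused by loss-of-function mutations in *TSC1* (hamartin) or *TSC2*
(tuberin); the two proteins, with TBC1D7, form a complex whose RHEB-GAP
activity restrains mTORC1. Renal angiomyolipoma (RAML) is the most common
renal manifestation and a major cause of mortality in TSC. Genotype-phenotype
correlation studies ask whether the *kind* and *location* of a patient's
mutation predict RAML: mutation type (missense, nonsense, frameshift,
splice-site, in-frame indel, large-fragment rearrangement), the
protein-truncating (PT) versus non-truncating (NT) dichotomy, and position
relative to the proteins' functional domains.

`tscgp` implements that analysis as a reusable, tested pipeline: one row of
input per patient (gene, coding-DNA HGVS description, optional protein-level
note, sex, RAML status), and as output a set of exposure-by-RAML 2x2
comparisons with rule-selected tests, Woolf odds-ratio confidence intervals
and crude logistic odds ratios.

## Reference coordinates

Variants are interpreted against *TSC1* (NM_000368.4; 23 exons, exons 1-2
non-coding; CDS 3495 nt, 1164 aa) and *TSC2* (NM_000548.3; 41 coding exons
plus one non-coding guiding exon; CDS 5424 nt, 1807 aa). Domains with
published residue ranges: hamartin's TMD (aa 127-144, exon 6) and CCD
(aa 730-996, exons 18-22), with TID defined only by exons 8-11; tuberin's
LZD (81-98), CCD1 (346-371), CCD2 (1008-1021), TAD1 (1163-1259, exons
29-30), GAPD (1517-1674), TAD2 (1690-1744) and CaBD (1740-1755). TAD2 and
CaBD overlap at residues 1740-1744, so hits on either are analysed under the
merged label `TAD2+CaBD`. Regions: *TSC1* is split N-/C-terminal at exon 15;
*TSC2* into HID-TID (exons 1-22), the middle region (23-33) and the GAP
region (34-41).

The literature states these domain placements but not exon boundary
coordinates (it defers to the LOVD database). The packaged exon tables under
`inst/extdata/reference_synthetic/` therefore carry **synthetic boundaries**:
constructed once to satisfy every stated constraint (spans tile the CDS;
each domain's residue range, converted by `3*(aa-1)+1 .. 3*aa`, falls within
its stated exons; `protein_length == cds_length/3 - 1`), and validated on
every load by `validate_reference()`. They are replaceable configuration —
`load_reference(gene, dir = ...)` accepts any directory with the same file
layout — and none of the headline association results depend on where the
boundaries fall, only exon-level annotations do.

Exact equality between residue-based and exon-based domain assignment is
impossible in principle (exons are coarser than residue ranges: exon 3 of
*TSC2* strictly contains LZD's codons), so assignment is by residue interval
wherever one exists, by exon interval only for TID, and the tested
consistency property is two-sided: a residue-based hit always lies within
the domain's stated exon range, and a variant outside those exons is never
a hit.

## Variant model

`parse_hgvs_c()` supports the c.-notation forms a curated cohort table
actually contains — substitution, deletion, duplication, insertion, delins,
and a single intronic offset on substitutions (`c.5068+1G>T`) — and rejects
the rest with typed errors (malformed, out-of-range, unsupported-form).
Parsing normalises whitespace and case and round-trips through
`format_hgvs_c()`. Records carrying two or more variants are rejected at
ingest, mirroring the curation practice of excluding patients whose
pathogenic mutation cannot be determined uniquely; no tie-break is invented.

Classification (`classify_mutation_type()`) is deterministic with explicit,
configurable parameters:

* **Splice window** (default ±2 nt): the canonical donor/acceptor
  dinucleotides. The literature never defines "splice-site mutation"; ±2 is
  the conservative reading. Larger offsets count as splice-site only when
  the declared source label says so; a deep-intronic substitution with no
  label is still called splice-site (the taxonomy has no intronic class and
  a missense call would be actively wrong) but carries a low-confidence
  flag.
* **Large-fragment rule** (default: affected span covers ≥ 1 entire exon or
  ≥ 50 nt): matches the usual indel-versus-LGR convention; published large
  fragments are multi-exon deletions/duplications.
* Remaining indels split frameshift / in-frame by `length_change %% 3`.
* Substitutions resolve missense versus nonsense from the declared
  protein-level note (`Ter`/`*`/`X` means stop). With no note the call is
  missense with a low-confidence flag — never a silent guess — or an error
  in strict mode. A variant that is simultaneously splice-affecting and
  missense (e.g. a substitution at an exon's last base) is classified by its
  declared source label, matching single-type tallies.

PT = {frameshift, splice-site, nonsense, large-fragment};
NT = {missense, in-frame}. The map is total and exclusive.

Domain membership counts the lesion **at its own position**: published
domain tables contain nonsense and frameshift mutations located *in* a
domain, not every truncating variant upstream of it, so downstream-loss
propagation is off by default (`propagate` option available). Multi-exon
variants take the region of their 5'-most exon and are flagged ambiguous
when they span a region boundary; this only matters for large fragments,
which are excluded from the domain/region analyses anyway. Exon 15 itself
is counted N-terminal ("split by exon 15" names no side); the choice is
configurable and affects only *TSC1* region tallies.

## Statistics

All comparisons are 2x2 with the fixed orientation a = exposed & RAML,
b = exposed & non-RAML, c = unexposed & RAML, d = unexposed & non-RAML.

* **Test selection** (`select_test()`): Fisher's exact test when any
  expected count is < 1 *or* N < 40; else the continuity-corrected
  chi-square when any expected count is < 5; else the plain chi-square.
  The Fisher condition is evaluated first; the rules are published as a
  sequence without explicit precedence, and this order reproduces every
  published method marker.
* **Chi-square**: closed form `N(ad-bc)^2 / (r1 r2 c1 c2)`; the Yates
  statistic floors `|ad-bc| - N/2` at zero (required to reproduce a
  published p = 1 on a near-null corrected table).
* **Fisher**: two-sided by the probability-mass rule — the sum of
  hypergeometric probabilities of all margin-preserving tables no more
  probable than the observed one, with a 1e-7 relative tie tolerance (the
  dominant software convention; the choice of two-sided rule is not
  published). Tested exhaustively against an independent enumeration
  oracle on all 635,375 tables with N ≤ 60.
* **Odds ratios**: Woolf interval `exp(ln OR ± z sqrt(1/a+1/b+1/c+1/d))`.
  Any zero cell leaves the OR undefined (reported as a dash, as published
  for an empty domain row); the Haldane-Anscombe +0.5 mode is opt-in and
  flagged. The crude logistic OR is the `glm` binomial fit of
  `outcome ~ exposure`; for a saturated 2x2 it must equal the cross-product
  OR and Woolf CI, so the IRLS tolerance is tightened (`epsilon = 1e-16`)
  and the identity is asserted to 1e-6 relative in the tests. A zero cell
  is separation and raises a typed error rather than returning a
  pseudo-estimate.
* Multiple testing: none by default (published p-values are raw); a
  Benjamini-Hochberg column can be requested as annotation.

CIs use `qnorm(0.975)` = 1.95996; tables produced with z = 1.96 differ in
the third decimal for very wide intervals, which is why printed-precision
comparisons in the tests allow half a printed unit plus 0.1% relative.

## The reference-cohort fixture

The underlying 261-patient cohort is published only as category counts, not
patient-level data. `paper_cohort()` rebuilds a deterministic patient-level
cohort from those counts: 54 *TSC1* / 207 *TSC2*; the full mutation-type by
RAML tallies per gene; the *TSC2* functional-domain by RAML table on the
large-fragment-excluded set (denominators 96 = 104 − 8 and 100 = 103 − 3);
and the sex margins (85 F / 63 M / 113 unknown). Positions inside each
targeted interval are synthetic (evenly spread); every count above is
recovered by running the real annotation stack, not by construction
shortcuts, and the test suite asserts it.

Three published numbers are knowingly not reproduced, because they are
internally inconsistent:

* the *TSC1* nonsense row's OR (1.6) is the reciprocal of the value its own
  counts give under the stated orientation (0.625, CI 0.192-2.034);
* the PT row's CI lower bound (0.13) cannot contain the printed OR 0.067;
  the Woolf bound computes to 0.013 and is asserted as such;
* the *TSC2* RAML region split (HID-TID/middle/GAP = 41/34/21 of 96) is
  incompatible with the same table's domain counts — GAPD (8) plus
  TAD2+CaBD (14) alone place 22 RAML mutations in GAP-region exons — so the
  fixture yields 40/34/22. Likewise, only the TAD1 row of the published
  secondary logistic p-value column is reproducible as a crude Wald p
  (0.019); the other entries match no crude quantity this package computes.

## The synthetic-cohort generator

`simulate_cohort()` draws gene (fixed sizes), sex, mutation type
(per-gene probabilities), and a variant emitted by `generate_hgvs()` —
whose round-trip contract (generated variants classify back to the intended
type) is property-tested — then derives each record's category labels by
running the real annotation stack and draws RAML from a logistic model:
`logit P(RAML) = baseline + sum of matching effects`. Effects are additive
log odds ratios with no interactions, matching the analysis model. Defaults
are the reference cohort's conditions: sizes 54/207, observed type
frequencies, 57.4% female, baseline prevalence 0.48, and the published
effect sizes (female OR 2.474, TAD1 OR 3.519). A single seeded generator is
threaded through all draws in a documented order (sex; per-gene types;
per-type variants; outcomes), so identical configurations give identical
cohorts and the caller's RNG state is untouched.

What the generator does **not** emulate — mutational hotspots, CpG bias,
the ascertainment bias of literature-derived cohorts, missing-data
structure, within-family correlation — bounds what passing tests show: the
pipeline recovers the parameters of its own generative model and holds its
nominal error rate under that model, not that real cohorts satisfy the
model.

`recovery_experiment()` repeats simulate-estimate cycles and reports mean
log-OR, bias, 95% CI coverage and rejection rate; zero-cell repetitions
fall back to the Haldane-adjusted estimate and are counted.

## Problem sizes and numerics

The shipped experiments use: exhaustive Fisher validation at N ≤ 60;
1,000 random tables for the logistic/Woolf identity; 10,000 simulated null
tables of n = 200 for the test-size property; 20,000 synthetic patients for
single-shot TAD1 recovery (uniform positions put ~5% of substitutions in
TAD1, giving ~1,000 exposed); and 1,000 repetitions of n = 200 for the
type-I-error experiment. These sizes give Monte-Carlo error comfortably
inside the asserted bounds (e.g. rejection-rate SE ≈ 0.007 at 1,000 reps)
while the full suite runs in about 90 seconds.

## Worked example

```{r example}
rep <- analyze(paper_cohort())
subset(rep$comparisons, label %in% c("female vs male", "TAD1"),
       select = c(label, a, b, c, d, method, p_value, or, ci_low, ci_high))
```

## Limitations

Substitution consequence calling relies on the declared protein note (no
CDS sequence is shipped, so translation is not attempted); cohorts without
protein notes get low-confidence missense calls. Only crude (univariable)
associations are computed — the published analysis itself could not adjust
for confounders for lack of covariate data — and r-by-c tables, exact
logistic regression and severity grading are out of scope. Exon-level
annotation inherits the synthetic boundary caveat above.
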
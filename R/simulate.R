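# Synthetic case-control cohort generator. The generative model is the one
# the association analysis assumes: category memberships (sex, gene,
# mutation type, PT/NT, domains, region) act additively on the log-odds of
# RAML, with no interactions. Variants are emitted as HGVS strings and
# pushed through the package's real annotation stack before the phenotype is
# drawn, so classification and annotation are part of the generative loop
# (round-trip contract), not assumed.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the reference cohort's structure: 54 TSC1 / 207 TSC2
#' patients, per-gene mutation-type frequencies equal to the observed ones,
#' a 57.4 percent female share among known-sex patients, a baseline RAML
#' log-odds of `qlogis(0.48)` (the observed prevalence), and the published
#' effects for female sex (OR 2.474) and TAD1 (OR 3.519).
#'
#' @param n_tsc1,n_tsc2 Patients per gene.
#' @param type_probs Named list with elements `TSC1`, `TSC2`: probability
#'   vectors over the six mutation types (must each sum to 1 within 1e-9).
#' @param position_dist `"uniform"` (uniform over the CDS) or `"per_exon"`
#'   (exon drawn uniformly, then position uniform within it).
#' @param sex_prob_female Probability of female sex.
#' @param baseline_logit Log-odds of RAML for a record in no effect category.
#' @param effects Named numeric vector of log odds ratios; names are matched
#'   against each record's derived category labels (sex, gene, mutation
#'   type, `PT`/`NT`, domain labels, region label).
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tsc1 = 54L, n_tsc2 = 207L,
                       type_probs = list(
                         TSC1 = c(missense = 13, nonsense = 18,
                                  frameshift = 19, splice_site = 0,
                                  in_frame = 0, large_fragment = 4) / 54,
                         TSC2 = c(missense = 59, nonsense = 40,
                                  frameshift = 63, splice_site = 24,
                                  in_frame = 10, large_fragment = 11) / 207),
                       position_dist = c("uniform", "per_exon"),
                       sex_prob_female = 85 / 148,
                       baseline_logit = stats::qlogis(0.48),
                       effects = c(female = log(2.474), TAD1 = log(3.519)),
                       seed = 1L) {
  position_dist <- match.arg(position_dist)
  stopifnot(n_tsc1 >= 0, n_tsc2 >= 0,
            sex_prob_female >= 0, sex_prob_female <= 1)
  for (g in c("TSC1", "TSC2")) {
    p <- type_probs[[g]]
    stopifnot(setequal(names(p), MUTATION_TYPES), all(p >= 0))
    if (abs(sum(p) - 1) > 1e-9) {
      stop("type_probs$", g, " must sum to 1", call. = FALSE)
    }
  }
  if (length(effects) > 0L && is.null(names(effects))) {
    stop("effects must be a named numeric vector", call. = FALSE)
  }
  structure(list(n_tsc1 = as.integer(n_tsc1), n_tsc2 = as.integer(n_tsc2),
                 type_probs = type_probs, position_dist = position_dist,
                 sex_prob_female = sex_prob_female,
                 baseline_logit = baseline_logit, effects = effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sample_positions <- function(n, ref, position_dist) {
  if (n == 0L) return(integer(0))
  if (position_dist == "uniform") {
    sample.int(ref$cds_length, n, replace = TRUE)
  } else {
    cex <- coding_exons(ref)
    e <- sample.int(nrow(cex), n, replace = TRUE)
    cex$cds_start[e] +
      floor(runif(n) * (cex$cds_end[e] - cex$cds_start[e] + 1L))
  }
}

#' Generate HGVS descriptions of a given mutation type
#'
#' Emits syntactically valid `c.` descriptions that the package's own
#' classifier maps back to `type` (round-trip contract): missense/nonsense
#' as substitutions with a matching declared protein consequence, frameshift
#' as 2-nt deletions, in-frame as 3-nt deletions, splice-site as
#' substitutions at a random exon boundary with offset +/-1 or +/-2, and
#' large-fragment as deletions of one or more entire exons. Draws from the
#' current RNG state.
#'
#' @param n Number of variants.
#' @param type One of the six mutation types.
#' @param gene `"TSC1"` or `"TSC2"`.
#' @param ref Reference tables (defaults to packaged).
#' @param position_dist Position distribution for point lesions.
#' @return Data frame with columns `hgvs_c`, `hgvs_p`.
#' @export
generate_hgvs <- function(n, type, gene, ref = load_reference(gene),
                          position_dist = "uniform") {
  type <- match.arg(type, MUTATION_TYPES)
  if (n == 0L) {
    return(data.frame(hgvs_c = character(0), hgvs_p = character(0),
                      stringsAsFactors = FALSE))
  }
  cex <- coding_exons(ref)
  p_note <- rep(NA_character_, n)
  if (type %in% c("missense", "nonsense")) {
    pos <- sample_positions(n, ref, position_dist)
    hgvs <- sprintf("c.%dG>A", pos)
    res <- ceiling(pos / 3)
    p_note <- if (type == "nonsense") sprintf("p.(Trp%dTer)", res) else
      sprintf("p.(Gly%dAsp)", res)
  } else if (type == "frameshift") {
    pos <- pmin(sample_positions(n, ref, position_dist), ref$cds_length - 1L)
    hgvs <- sprintf("c.%d_%ddel", pos, pos + 1L)
  } else if (type == "in_frame") {
    pos <- pmin(sample_positions(n, ref, position_dist), ref$cds_length - 2L)
    hgvs <- sprintf("c.%d_%ddel", pos, pos + 2L)
  } else if (type == "splice_site") {
    # boundaries: exon ends (donor side) except the last exon's
    ends <- cex$cds_end[-nrow(cex)]
    anchor <- ends[sample.int(length(ends), n, replace = TRUE)]
    off <- sample(c(1L, 2L), n, replace = TRUE)
    hgvs <- sprintf("c.%d+%dG>A", anchor, off)
  } else { # large_fragment
    i <- sample.int(nrow(cex) - 1L, n, replace = TRUE)
    j <- pmin(i + sample.int(3L, n, replace = TRUE), nrow(cex))
    hgvs <- sprintf("c.%d_%ddel", cex$cds_start[i], cex$cds_end[j])
  }
  data.frame(hgvs_c = hgvs, hgvs_p = p_note, stringsAsFactors = FALSE)
}

#' Simulate a synthetic cohort under the logistic generative model
#'
#' Draw order (fixed, so runs are reproducible under the configured seed):
#' sex for all records; then, per gene, mutation types and the variant
#' descriptions per type; then the RAML outcome. Category labels that feed
#' the linear predictor are derived by running [annotate_cohort()] on the
#' generated variants, and RAML is Bernoulli with
#' `plogis(baseline_logit + sum of matching effects)`.
#'
#' @param cfg A [sim_config()].
#' @param annotate Keep the annotation columns on the returned cohort
#'   (default; set `FALSE` to return the bare record schema).
#' @return Annotated cohort data frame with an additional `linpred` column.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_tsc1 = 5, n_tsc2 = 20, seed = 42))
#' table(coh$mutation_type)
simulate_cohort <- function(cfg, annotate = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(cfg$seed)

  n <- cfg$n_tsc1 + cfg$n_tsc2
  gene <- rep(c("TSC1", "TSC2"), c(cfg$n_tsc1, cfg$n_tsc2))
  sex <- ifelse(runif(n) < cfg$sex_prob_female, "female", "male")
  hgvs_c <- character(n)
  hgvs_p <- rep(NA_character_, n)
  type_drawn <- character(n)
  for (g in c("TSC1", "TSC2")) {
    i <- which(gene == g)
    if (length(i) == 0L) next
    probs <- cfg$type_probs[[g]][MUTATION_TYPES]
    type_drawn[i] <- sample(MUTATION_TYPES, length(i), replace = TRUE,
                            prob = probs)
    ref <- load_reference(g)
    for (ty in MUTATION_TYPES) {
      j <- i[type_drawn[i] == ty]
      if (length(j) == 0L) next
      v <- generate_hgvs(length(j), ty, g, ref, cfg$position_dist)
      hgvs_c[j] <- v$hgvs_c
      hgvs_p[j] <- v$hgvs_p
    }
  }

  coh <- data.frame(patient_id = sprintf("S%05d", seq_len(n)), gene = gene,
                    transcript = ifelse(gene == "TSC1", "NM_000368.4",
                                        "NM_000548.3"),
                    hgvs_c = hgvs_c, hgvs_p = hgvs_p, sex = sex,
                    raml = NA, source = "synthetic",
                    stringsAsFactors = FALSE)
  ann <- annotate_cohort(coh)
  labels <- Map(function(sx, g, ty, tr, dom, rg) {
    c(sx, g, ty, tr, if (nzchar(dom)) strsplit(dom, ";", fixed = TRUE)[[1]],
      rg)
  }, ann$sex, ann$gene, ann$mutation_type, ann$truncation, ann$domains,
  ann$region)
  eff <- cfg$effects
  linpred <- cfg$baseline_logit + vapply(labels, function(lb) {
    sum(eff[names(eff) %in% lb])
  }, numeric(1))
  ann$raml <- rbinom(n, 1L, plogis(linpred)) == 1L
  ann$linpred <- linpred
  if (!annotate) ann <- ann[, COHORT_COLUMNS, drop = FALSE]
  ann
}

#' Repeated-simulation parameter recovery and error-rate experiment
#'
#' Runs [simulate_cohort()] `n_reps` times (each repetition gets its own
#' seed derived from `seed`), estimates the exposure's log odds ratio from
#' the simulated cohort each time, and summarises: mean log-OR estimate and
#' bias against the configured truth, empirical coverage of the 95 percent
#' Woolf CI, and the rejection rate of the rule-selected test at alpha =
#' 0.05. Repetitions with a zero cell use the Haldane-Anscombe adjusted
#' estimate and are flagged in the `n_adjusted` column.
#'
#' @param cfg A [sim_config()]; its `seed` element is ignored in favour of
#'   per-repetition seeds.
#' @param exposure Category label whose effect is estimated (e.g.
#'   `"female"`, `"TAD1"`, `"missense"`, `"PT"`).
#' @param n_reps Number of repetitions; 0 returns an empty summary.
#' @param seed Master seed for the experiment.
#' @param alpha Test size for the rejection-rate column.
#' @return One-row data frame: `exposure`, `n_reps`, `true_log_or`,
#'   `mean_log_or`, `bias_log_or`, `coverage`, `rejection_rate`,
#'   `n_adjusted`.
#' @export
recovery_experiment <- function(cfg, exposure, n_reps, seed = 1L,
                                alpha = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 0)
  empty <- data.frame(exposure = character(0), n_reps = integer(0),
                      true_log_or = numeric(0), mean_log_or = numeric(0),
                      bias_log_or = numeric(0), coverage = numeric(0),
                      rejection_rate = numeric(0), n_adjusted = integer(0),
                      stringsAsFactors = FALSE)
  if (n_reps == 0L) return(empty)
  true_log_or <- if (exposure %in% names(cfg$effects)) {
    unname(cfg$effects[[exposure]])
  } else 0
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)

  est <- cover <- reject <- rep(NA_real_, n_reps)
  adjusted <- rep(FALSE, n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- rep_seeds[r]
    coh <- simulate_cohort(cfg_r)
    exposed <- coh$sex == exposure | coh$gene == exposure |
      coh$mutation_type == exposure | coh$truncation == exposure |
      coh$region == exposure | has_domain(coh$domains, exposure)
    t <- build_table(coh, exposed)
    or <- odds_ratio_woolf(t, alpha = alpha, haldane = TRUE)
    adjusted[r] <- or$adjusted
    est[r] <- log(or$or)
    cover[r] <- or$ci_low <= exp(true_log_or) & exp(true_log_or) <= or$ci_high
    reject[r] <- if (isTRUE(attr(t, "degenerate"))) NA else
      test_2x2(t)$p_value < alpha
  }
  data.frame(exposure = exposure, n_reps = as.integer(n_reps),
             true_log_or = true_log_or, mean_log_or = mean(est),
             bias_log_or = mean(est) - true_log_or,
             coverage = mean(cover), rejection_rate = mean(reject, na.rm = TRUE),
             n_adjusted = sum(adjusted), stringsAsFactors = FALSE)
}

#' Read a simulation configuration from a JSON or YAML file
#'
#' The file may specify any subset of [sim_config()]'s fields; omitted
#' fields keep their defaults. `type_probs` and `effects` are given as
#' name-value maps. YAML support requires the `yaml` package.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configurations requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$type_probs)) {
    raw$type_probs <- lapply(raw$type_probs, unlist)
  }
  if (!is.null(raw$effects)) raw$effects <- unlist(raw$effects)
  bad <- setdiff(names(raw), names(formals(sim_config)))
  if (length(bad) > 0L) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}
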
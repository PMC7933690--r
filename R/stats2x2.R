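# 2x2 contingency engine. Orientation contract throughout: rows = exposure
# (yes/no), columns = outcome (RAML yes/no):
#   a = exposed & RAML      b = exposed & no RAML
#   c = unexposed & RAML    d = unexposed & no RAML

#' Construct a 2x2 exposure-by-outcome table
#'
#' @param a,b,c,d Non-negative integer counts (a = exposed & outcome,
#'   b = exposed & no outcome, c = unexposed & outcome, d = unexposed & no
#'   outcome).
#' @return An object of class `table2x2`.
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("table total must be >= 1", call. = FALSE)
  structure(as.list(cells), n = sum(cells), class = "table2x2")
}

#' @export
as.matrix.table2x2 <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), 2L, 2L,
         dimnames = list(exposure = c("yes", "no"),
                         outcome = c("yes", "no")))
}

#' @export
print.table2x2 <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

#' Expected counts under independence
#'
#' `E[i, j] = row_i total * column_j total / N`; the entries always sum to N.
#'
#' @param t A [table2x2()].
#' @return A 2x2 numeric matrix in the same orientation as `as.matrix(t)`.
#' @export
expected_counts <- function(t) {
  m <- as.matrix(t)
  outer(rowSums(m), colSums(m)) / sum(m)
}

#' Select the association test for a 2x2 table
#'
#' Decision rule: Fisher's exact test when any expected count is below one
#' or the total sample size is below 40 (this condition takes precedence);
#' otherwise the continuity-corrected chi-square test when any expected
#' count is below 5; otherwise the plain chi-square test.
#'
#' @param t A [table2x2()].
#' @return `"fisher_exact"`, `"chi_square_yates"` or `"chi_square"`.
#' @export
#' @examples
#' select_test(table2x2(47, 38, 21, 42))  # "chi_square"
#' select_test(table2x2(2, 3, 4, 5))      # "fisher_exact"
select_test <- function(t) {
  e <- expected_counts(t)
  n <- attr(t, "n")
  if (min(e) < 1 || n < 40) {
    "fisher_exact"
  } else if (min(e) < 5) {
    "chi_square_yates"
  } else {
    "chi_square"
  }
}

#' Pearson chi-square test for a 2x2 table (closed form)
#'
#' Uncorrected statistic `N (ad - bc)^2 / (r1 r2 c1 c2)`; with Yates'
#' continuity correction, `N (max(|ad - bc| - N/2, 0))^2 / (r1 r2 c1 c2)`
#' (floored at zero, so tables with `|ad - bc| <= N/2` give p = 1). The
#' p-value is the df = 1 chi-square upper tail.
#'
#' @param t A [table2x2()].
#' @param yates Apply the continuity correction.
#' @return A list of class `tsc_test`: `method`, `statistic`, `p_value`.
#' @export
#' @examples
#' chi_square_test(table2x2(47, 38, 21, 42))  # p ~ 0.008
chi_square_test <- function(t, yates = FALSE) {
  m <- as.matrix(t)
  r <- rowSums(m); cc <- colSums(m); n <- sum(m)
  if (any(r == 0) || any(cc == 0)) {
    tscgp_error("tscgp_degenerate_table",
                "chi-square test undefined for a table with a zero margin")
  }
  dif <- abs(t$a * t$d - t$b * t$c)
  if (yates) dif <- max(dif - n / 2, 0)
  stat <- n * dif^2 / prod(c(r, cc))
  structure(list(method = if (yates) "chi_square_yates" else "chi_square",
                 statistic = stat,
                 p_value = pchisq(stat, df = 1L, lower.tail = FALSE)),
            class = "tsc_test")
}

#' Fisher's exact test for a 2x2 table (two-sided, probability-mass rule)
#'
#' Two-sided p-value by the probability-mass rule: the sum, over all tables
#' with the observed margins, of the hypergeometric probabilities of tables
#' no more probable than the observed one (ties compared within a relative
#' tolerance of 1e-7). Degenerate margins give p = 1.
#'
#' @param t A [table2x2()].
#' @return A list of class `tsc_test`: `method`, `statistic` (`NA`),
#'   `p_value`.
#' @export
#' @examples
#' fisher_exact_test(table2x2(5, 0, 0, 5))  # p = 2/252
fisher_exact_test <- function(t) {
  n <- attr(t, "n")
  r1 <- t$a + t$b
  c1 <- t$a + t$c
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- probs[match(t$a, support)]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  structure(list(method = "fisher_exact", statistic = NA_real_, p_value = p),
            class = "tsc_test")
}

#' Run the rule-selected association test
#'
#' Applies [select_test()] and dispatches to the matching test. The result
#' carries a report `marker`: `"&"` for continuity-corrected tests (the
#' convention used in published tables) and `"F"` for Fisher's exact test.
#'
#' @param t A [table2x2()].
#' @return A `tsc_test` with an extra `marker` element.
#' @export
test_2x2 <- function(t) {
  method <- select_test(t)
  res <- switch(method,
                chi_square = chi_square_test(t, yates = FALSE),
                chi_square_yates = chi_square_test(t, yates = TRUE),
                fisher_exact = fisher_exact_test(t))
  res$marker <- switch(method, chi_square = "", chi_square_yates = "&",
                       fisher_exact = "F")
  res
}

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' `OR = ad / (bc)`; the CI is `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c +
#' 1/d))`, log-symmetric about the point estimate. Any zero cell leaves the
#' OR undefined by default (reported as such, the way published tables print
#' a dash); the optional Haldane-Anscombe mode adds 0.5 to every cell and
#' flags the adjustment.
#'
#' @param t A [table2x2()].
#' @param alpha Two-sided error rate (default 0.05 for a 95 percent CI).
#' @param haldane Apply the 0.5-cell correction when a cell is zero.
#' @return A list of class `or_result`: `or`, `ci_low`, `ci_high`,
#'   `se_log_or`, `alpha`, `method = "woolf"`, `defined`, `adjusted`.
#' @export
#' @examples
#' odds_ratio_woolf(table2x2(47, 38, 21, 42))  # OR 2.474 (1.258-4.864)
odds_ratio_woolf <- function(t, alpha = 0.05, haldane = FALSE) {
  cells <- c(t$a, t$b, t$c, t$d)
  adjusted <- FALSE
  if (any(cells == 0)) {
    if (!haldane) {
      return(structure(list(or = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, se_log_or = NA_real_,
                            alpha = alpha, method = "woolf",
                            defined = FALSE, adjusted = FALSE),
                       class = "or_result"))
    }
    cells <- cells + 0.5
    adjusted <- TRUE
  }
  or <- cells[1L] * cells[4L] / (cells[2L] * cells[3L])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - alpha / 2)
  structure(list(or = or, ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se), se_log_or = se,
                 alpha = alpha, method = "woolf", defined = TRUE,
                 adjusted = adjusted),
            class = "or_result")
}

#' Crude odds ratio from binary logistic regression
#'
#' Maximum-likelihood fit of `outcome ~ exposure` (binomial logit) on the
#' table's N observations. For a saturated 2x2 model the exponentiated slope
#' equals the cross-product odds ratio and the Wald interval equals the
#' Woolf interval, so this route cross-checks [odds_ratio_woolf()] while
#' additionally providing the Wald p-value.
#'
#' @param t A [table2x2()]; all four cells must be positive (a zero cell is
#'   complete or quasi-complete separation and raises
#'   `tscgp_separation`).
#' @param alpha Two-sided error rate.
#' @return An `or_result` with `method = "logistic_wald"` and an extra
#'   `p_value` element.
#' @export
#' @examples
#' logistic_crude_or(table2x2(15, 81, 5, 95))  # OR 3.519, p ~ 0.019
logistic_crude_or <- function(t, alpha = 0.05) {
  if (any(c(t$a, t$b, t$c, t$d) == 0)) {
    tscgp_error("tscgp_separation",
                paste("a zero cell separates the outcome; the crude logistic",
                      "odds ratio does not converge (use odds_ratio_woolf",
                      "with haldane = TRUE for an adjusted estimate)"))
  }
  df <- data.frame(outcome = c(1, 0, 1, 0), exposure = c(1, 1, 0, 0),
                   w = c(t$a, t$b, t$c, t$d))
  fit <- suppressWarnings(glm(outcome ~ exposure, family = binomial(),
                              data = df, weights = w,
                              control = stats::glm.control(epsilon = 1e-16,
                                                           maxit = 100)))
  est <- coef(summary(fit))["exposure", ]
  z <- qnorm(1 - alpha / 2)
  structure(list(or = exp(est[["Estimate"]]),
                 ci_low = exp(est[["Estimate"]] - z * est[["Std. Error"]]),
                 ci_high = exp(est[["Estimate"]] + z * est[["Std. Error"]]),
                 se_log_or = est[["Std. Error"]], alpha = alpha,
                 method = "logistic_wald", defined = TRUE, adjusted = FALSE,
                 p_value = est[["Pr(>|z|)"]]),
            class = "or_result")
}

#' @export
print.tsc_test <- function(x, ...) {
  cat(sprintf("<tsc_test> %s: statistic = %s, p = %.4g\n", x$method,
              if (is.na(x$statistic)) "-" else sprintf("%.4g", x$statistic),
              x$p_value))
  invisible(x)
}

#' @export
print.or_result <- function(x, ...) {
  if (!isTRUE(x$defined)) {
    cat(sprintf("<or_result> %s: undefined (zero cell)\n", x$method))
  } else {
    cat(sprintf("<or_result> %s: OR %.3f, %d%% CI (%.3f-%.3f)%s\n", x$method,
                x$or, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
                if (isTRUE(x$adjusted)) " [Haldane-adjusted]" else ""))
  }
  invisible(x)
}
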
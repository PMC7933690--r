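test_that("expected counts follow the margin product rule", {
  e <- expected_counts(table2x2(47, 38, 21, 42))
  expect_equal(min(e), 63 * 68 / 148)
  expect_equal(sum(e), 148)
  expect_equal(expected_counts(table2x2(1, 1, 1, 1)),
               matrix(1, 2, 2), ignore_attr = TRUE)
  e <- expected_counts(table2x2(0, 0, 5, 5))
  expect_equal(e[1, ], c(yes = 0, no = 0))
  expect_error(table2x2(0, 0, 0, 0), "total")
  expect_error(table2x2(-1, 2, 3, 4), "non-negative")
})

test_that("test selection: Fisher below N=40 or expected<1, Yates below expected 5", {
  expect_equal(select_test(table2x2(47, 38, 21, 42)), "chi_square")
  expect_equal(select_test(table2x2(1, 95, 4, 96)), "chi_square_yates")
  expect_equal(select_test(table2x2(2, 3, 4, 5)), "fisher_exact")
  # Fisher precedence: large N but a tiny expected cell
  expect_equal(select_test(table2x2(1, 0, 60, 80)), "fisher_exact")
})

test_that("chi-square closed form reproduces known p-values; Yates floors at zero", {
  r <- chi_square_test(table2x2(47, 38, 21, 42))
  expect_equal(r$statistic, 148 * (47 * 42 - 38 * 21)^2 / (85 * 63 * 68 * 80))
  expect_equal(round(r$p_value, 3), 0.008)

  r <- chi_square_test(table2x2(3, 93, 3, 97), yates = TRUE)
  expect_equal(r$statistic, 0)  # |ad-bc| = 12 < N/2 = 98
  expect_equal(r$p_value, 1)

  r <- chi_square_test(table2x2(1, 95, 4, 96), yates = TRUE)
  expect_equal(round(r$p_value, 2), 0.39)

  expect_error(chi_square_test(table2x2(0, 0, 5, 5)),
               class = "tscgp_degenerate_table")
})

test_that("chi-square agrees with stats::chisq.test on random tables", {
  set.seed(41)
  for (i in 1:200) {
    t <- random_table()
    m <- as.matrix(t)
    for (yates in c(FALSE, TRUE)) {
      ours <- chi_square_test(t, yates = yates)
      theirs <- suppressWarnings(chisq.test(m, correct = yates))
      expect_equal(ours$statistic, unname(theirs$statistic), tolerance = 1e-12)
      expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-12)
    }
  }
})

test_that("Yates statistic never exceeds the uncorrected statistic", {
  set.seed(42)
  for (i in 1:200) {
    t <- random_table()
    expect_lte(chi_square_test(t, TRUE)$statistic,
               chi_square_test(t, FALSE)$statistic)
  }
})

test_that("Fisher exact: hand-enumerated and cross-checked cases", {
  # margins 1/1: two equally probable tables, two-sided p = 1
  expect_equal(fisher_exact_test(table2x2(1, 0, 0, 1))$p_value, 1)
  # 10-choose-5 enumeration: the two extreme tables each have p = 1/252
  expect_equal(fisher_exact_test(table2x2(5, 0, 0, 5))$p_value, 2 / 252)
  # degenerate margins
  expect_equal(fisher_exact_test(table2x2(0, 0, 3, 4))$p_value, 1)

  set.seed(43)
  for (i in 1:200) {
    t <- random_table(15L)
    expect_equal(fisher_exact_test(t)$p_value,
                 fisher_oracle(t$a, t$b, t$c, t$d), tolerance = 1e-12)
    expect_equal(fisher_exact_test(t)$p_value,
                 fisher.test(as.matrix(t))$p.value, tolerance = 1e-7)
  }
})

test_that("Woolf odds ratio reproduces published values and is log-symmetric", {
  or <- odds_ratio_woolf(table2x2(47, 38, 21, 42))
  expect_printed(or$or, 2.474)
  expect_printed(or$ci_low, 1.258)
  expect_printed(or$ci_high, 4.864)
  expect_equal(log(or$ci_high) - log(or$or), log(or$or) - log(or$ci_low))

  or <- odds_ratio_woolf(table2x2(11, 2, 11, 30))
  expect_printed(or$or, 15)
  expect_printed(or$ci_low, 2.859)
  expect_printed(or$ci_high, 78.691)

  or <- odds_ratio_woolf(table2x2(1, 1, 1, 1))
  expect_equal(or$or, 1)
  expect_equal(or$ci_low * or$ci_high, 1)

  # zero cells: undefined by default, Haldane-Anscombe on request
  or <- odds_ratio_woolf(table2x2(0, 5, 5, 5))
  expect_false(or$defined)
  expect_true(is.na(or$or))
  or <- odds_ratio_woolf(table2x2(0, 5, 5, 5), haldane = TRUE)
  expect_true(or$adjusted)
  expect_equal(or$or, (0.5 * 5.5) / (5.5 * 5.5))
})

test_that("swapping exposure rows reciprocates the OR and its CI", {
  set.seed(44)
  for (i in 1:100) {
    t <- random_table()
    f <- odds_ratio_woolf(t)
    r <- odds_ratio_woolf(table2x2(t$c, t$d, t$a, t$b))
    expect_equal(r$or, 1 / f$or, tolerance = 1e-12)
    expect_equal(r$ci_low, 1 / f$ci_high, tolerance = 1e-12)
    expect_equal(r$ci_high, 1 / f$ci_low, tolerance = 1e-12)
  }
})

test_that("crude logistic OR equals the cross-product OR and Woolf CI", {
  lo <- logistic_crude_or(table2x2(15, 81, 5, 95))
  expect_printed(lo$or, 3.519)
  expect_printed(lo$ci_low, 1.226)
  expect_printed(lo$ci_high, 10.101)
  expect_equal(round(lo$p_value, 3), 0.019)

  lo <- logistic_crude_or(table2x2(2, 2, 2, 2))
  expect_equal(lo$or, 1, tolerance = 1e-9)
  expect_equal(lo$p_value, 1, tolerance = 1e-9)

  expect_error(logistic_crude_or(table2x2(0, 5, 5, 5)),
               class = "tscgp_separation")

  set.seed(45)
  for (i in 1:100) {
    t <- random_table()
    wo <- odds_ratio_woolf(t)
    lo <- logistic_crude_or(t)
    expect_equal(lo$or, wo$or, tolerance = 1e-6)
    expect_equal(lo$ci_low, wo$ci_low, tolerance = 1e-6)
    expect_equal(lo$ci_high, wo$ci_high, tolerance = 1e-6)
  }
})

test_that("p-values are probabilities and decrease in the chi-square statistic", {
  set.seed(46)
  stats <- ps <- numeric(0)
  for (i in 1:100) {
    t <- random_table()
    r <- chi_square_test(t)
    stats <- c(stats, r$statistic)
    ps <- c(ps, r$p_value, fisher_exact_test(t)$p_value)
  }
  expect_true(all(ps >= 0 & ps <= 1))
  o <- order(stats)
  expect_true(all(diff(pchisq(stats[o], 1, lower.tail = FALSE)) <= 1e-15))
})

test_that("rule-selected test holds its size under the null", {
  # 10,000 independent 2x2 tables of n = 200 under independence
  set.seed(47)
  tabs <- rmultinom(10000, 200, rep(0.25, 4))
  p <- apply(tabs, 2, function(x) {
    test_2x2(table2x2(x[1], x[2], x[3], x[4]))$p_value
  })
  rate <- mean(p < 0.05)
  # <= 0.05 plus ~2.5 Monte-Carlo standard errors
  expect_lte(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 10000))
})
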
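test_that("all-positive differences give the exact enumeration p-value", {
  res <- paired_wilcoxon(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$statistic, 21)
  expect_identical(res$method, "exact")
})

test_that("exact p matches brute-force sign enumeration, with and without ties", {
  set.seed(21)
  for (k in 1:40) {
    n <- sample(5:10, 1)
    x <- round(rnorm(n, 0, 2), sample(0:1, 1))  # rounding induces ties
    y <- round(rnorm(n, 0.5, 2), 1)
    if (all(x == y)) next
    got <- paired_wilcoxon(x, y)
    expect_equal(got$p_value, wilcoxon_enum_oracle(x - y), tolerance = 1e-12)
  }
})

test_that("exact p agrees with wilcox.test on tie-free data", {
  set.seed(33)
  for (k in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                               exact = TRUE))
    expect_equal(paired_wilcoxon(x, y)$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(8)
  x <- rnorm(25, 0.4); y <- rnorm(25)
  got <- paired_wilcoxon(x, y)
  expect_identical(got$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = FALSE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(paired_wilcoxon(1:6, 1:6), "all differences zero")
})

test_that("the gender 2x2 table gives the uncorrected chi-squared p of 0.01", {
  res <- chi2_2x2(matrix(c(4, 11, 11, 4), 2, byrow = TRUE))
  expect_equal(res$statistic, 30 * (4 * 4 - 11 * 11)^2 / (15 * 15 * 15 * 15),
               tolerance = 1e-12)
  expect_equal(round(res$statistic, 3), 6.533)
  expect_equal(round(res$p_value, 2), 0.01)
  balanced <- chi2_2x2(matrix(5, 2, 2))
  expect_equal(balanced$statistic, 0)
  expect_equal(balanced$p_value, 1)
})

test_that("chi-squared is symmetric and matches the expected-counts formula", {
  set.seed(4)
  for (k in 1:20) {
    tb <- matrix(sample(1:30, 4, TRUE), 2)
    ## suppress the small-expected-count approximation warning on tiny tables
    res <- suppressWarnings(chi2_2x2(tb))
    E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    expect_equal(res$statistic, sum((tb - E)^2 / E), tolerance = 1e-10)
    expect_equal(suppressWarnings(chi2_2x2(tb[2:1, ]))$statistic, res$statistic)
    expect_equal(suppressWarnings(chi2_2x2(tb[, 2:1]))$statistic, res$statistic)
    expect_equal(suppressWarnings(chi2_2x2(t(tb)))$statistic, res$statistic)
  }
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("Spearman rho is monotone-invariant and matches the rank oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_corr(x, 2 * x + 1)$statistic, 1)
  expect_equal(spearman_corr(x, -x^3)$statistic, -1)
  expect_equal(spearman_corr(x, 2 * x + 1)$p_value, 0)
  set.seed(14)
  for (k in 1:10) {
    xx <- round(rnorm(20), 1)  # ties likely
    yy <- round(rnorm(20) + 0.3 * xx, 1)
    got <- spearman_corr(xx, yy)
    expect_equal(got$statistic, spearman_rank_oracle(xx, yy), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(xx, yy, method = "spearman"))
    expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$statistic, spearman_corr(exp(xx), yy^3 + yy)$statistic,
                 tolerance = 1e-12)
  }
  expect_error(spearman_corr(rep(1, 8), rnorm(8)), "variance")
})

test_that("the Shapiro-Wilk gate is calibrated and powered", {
  expect_identical(shapiro_gate(rep(3, 10))$family, "nonparametric")
  expect_true(is.na(shapiro_gate(rep(3, 10))$normality_p))
  expect_error(shapiro_gate(rnorm(60)), "n <= 50")
  set.seed(6)
  rej_norm <- mean(replicate(1000, shapiro_gate(rnorm(30))$family == "nonparametric"))
  expect_lt(abs(rej_norm - 0.05), 0.02)
  rej_logn <- mean(replicate(200, shapiro_gate(rlnorm(30))$family == "nonparametric"))
  expect_gt(rej_logn, 0.5)
})

test_that("Bonferroni multiplies, caps at 1, never decreases", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.5, 4), 1)
  set.seed(2)
  p <- runif(20)
  for (m in c(20, 35)) {
    got <- bonferroni(p, m)
    expect_equal(got, pmin(1, m * p))
    expect_true(all(got >= p))
    expect_true(all(got <= 1))
  }
  expect_error(bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni(runif(5), m = 3), "family size")
})

test_that("identical groups yield NA p-values flagged not significant", {
  co <- simulate_cohort(8, seed = 5)
  co$metric_same <- rep(seq_len(8), each = 2)  # equal within every pair
  res <- run_cohort_comparison(co, c("metric_same", "hk_pct_responders"))
  row <- res$comparisons[res$comparisons$metric == "metric_same", ]
  expect_true(is.na(row$p_value))
  expect_false(row$significant)
})

test_that("cohort comparison gates, corrects within family, and correlates", {
  co <- simulate_cohort(15, effects = c(hk_pct_responders = -25), seed = 77)
  res <- run_cohort_comparison(co,
    c("hk_pct_responders", "hk_mean_amplitude_pct", "mito_volume_ratio"),
    covariates = c("age", "scopa_gi", "updrs3_off", "disease_duration_years"))
  expect_identical(unique(res$comparisons$family_size), 3L)
  expect_equal(res$comparisons$corrected_p,
               pmin(1, 3 * res$comparisons$p_value))
  expect_true(all(res$comparisons$test %in% c("paired_wilcoxon", "paired_t")))
  expect_identical(nrow(res$correlations), 12L)
  expect_error(run_cohort_comparison(co[-1, ], "hk_pct_responders"),
               "one PD and one control")
})

test_that("paired design holds its size and power at reduced scale", {
  null_any <- logical(50); detected <- logical(50)
  for (r in 1:50) {
    co <- simulate_cohort(15, seed = 300 + r)
    st <- run_cohort_comparison(co, c("hk_pct_responders",
                                      "mito_fluctuation_score_pct"))
    null_any[r] <- any(st$comparisons$significant)
    co2 <- simulate_cohort(15, effects = c(hk_pct_responders = -20),
                           seed = 600 + r)
    pw <- paired_wilcoxon(co2$hk_pct_responders[co2$group == "PD"],
                          co2$hk_pct_responders[co2$group == "control"])
    detected[r] <- pw$p_value < 0.05
  }
  expect_lte(mean(null_any), 0.10)
  expect_gte(mean(detected), 0.75)
})
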
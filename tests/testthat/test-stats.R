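test_that("pooled t-test matches the summary-statistic route and degenerate cases", {
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20, 1)
  a <- two_sample_t(x, y)
  b <- two_sample_t(summary = list(mean = c(mean(x), mean(y)),
                                   sd = c(sd(x), sd(y)), n = c(20, 20)))
  expect_equal(a$t, b$t)
  expect_equal(a$t, unname(t.test(x, y, var.equal = TRUE)$statistic))
  z <- two_sample_t(x, x)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  big <- two_sample_t(summary = list(mean = c(0, 1), sd = c(1, 1),
                                     n = c(1000, 1000)))
  expect_lt(big$p, 1e-10)
  expect_error(two_sample_t(rep(1, 5), rep(1, 5)), "pooled variance")
})

test_that("chi-square on contingency tables (no continuity correction)", {
  expect_equal(chi_square(rbind(c(10, 10), c(10, 10)))$chisq, 0)
  expect_equal(chi_square(rbind(c(20, 0), c(0, 20)))$chisq, 40)
  tab <- rbind(c(12, 5), c(8, 9))
  expect_equal(chi_square(tab)$chisq,
               unname(chisq.test(tab, correct = FALSE)$statistic))
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("Friedman test handles degenerate and clearly ordered data", {
  expect_equal(friedman_test(matrix(5, 6, 3))$statistic, 0)
  set.seed(2)
  m <- matrix(rnorm(30), 10)
  ordered <- cbind(m[, 1], m[, 1] + 10, m[, 3])
  expect_lt(friedman_test(ordered)$p, 0.05)
  # jointly permuting condition labels leaves the statistic unchanged
  expect_equal(friedman_test(m)$statistic,
               friedman_test(m[, c(3, 1, 2)])$statistic)
})

test_that("Spearman correlation is monotone-invariant and guards constants", {
  expect_equal(spearman(1:20, exp(1:20 / 3))$r, 1)
  expect_equal(spearman(1:20, rev(1:20))$r, -1)
  expect_error(spearman(rep(1, 10), 1:10), "constant")
  expect_error(spearman(1:3, 3:1), "n >= 4")
})

test_that("partial correlation recovers the population value and its limits", {
  set.seed(3)
  n <- 2000
  z <- rnorm(n)
  # construct x, y with partial correlation 0.5 given z
  e1 <- rnorm(n); e2 <- 0.5 * e1 + sqrt(1 - 0.25) * rnorm(n)
  x <- 0.7 * z + e1
  y <- 0.7 * z + e2
  pc <- partial_corr(x, y, z, method = "pearson")
  expect_gt(pc$r, 0.45); expect_lt(pc$r, 0.55)
  # independent covariate: partial ~ unconditional
  u <- rnorm(500); v <- 0.5 * u + rnorm(500) * sqrt(0.75); w <- rnorm(500)
  expect_lt(abs(partial_corr(u, v, w, method = "pearson")$r - cor(u, v)),
            0.05)
  # fully explained outcome
  expect_equal(partial_corr(x, z, z)$r, 0)
  expect_error(partial_corr(x, y, rep(1, n)), "collinear")
})

test_that("bootstrap CI is deterministic, degenerate on exact fits, calibrated on null data", {
  lin <- data.frame(x = 1:20, y = 3 * (1:20))
  ci <- bootstrap_ci(function(d) cor(d$x, d$y), lin, n_boot = 200, seed = 5)
  expect_equal(c(ci$lo, ci$hi), c(1, 1))
  expect_true(ci$significant)
  ci2 <- bootstrap_ci(function(d) cor(d$x, d$y), lin, n_boot = 200, seed = 5)
  expect_identical(ci, ci2)

  set.seed(6)
  flags <- vapply(1:60, function(i) {
    d <- data.frame(x = rnorm(50), y = rnorm(50))
    bootstrap_ci(function(dd) cor(dd$x, dd$y), d, n_boot = 200,
                 seed = i)$significant
  }, logical(1))
  expect_lte(mean(flags), 0.10)
  expect_error(bootstrap_ci(function(d) mean(d), 1:5), "at least 8")
})

test_that("Bonferroni adjustment clips at 1", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 30), 1)
  expect_equal(bonferroni(0, 100), 0)
  expect_error(bonferroni(c(0.1, 0.2), 1), "family size")
})

test_that("Lilliefors normality test keeps level and has power", {
  set.seed(7)
  expect_gt(ks_normality(rnorm(1000))$p, 0.05)
  expect_lt(ks_normality(rexp(1000))$p, 0.01)
  expect_error(ks_normality(rnorm(5)), "n >= 8")
  expect_error(ks_normality(rep(2, 20)), "constant")
})

test_that("group battery is invariant to subject order and reports a tidy table", {
  co <- simulate_cohort(cohort_spec(seed = 4))$cohort
  gb1 <- group_battery(co)
  gb2 <- group_battery(co[sample(nrow(co)), ])
  expect_equal(gb1$table$p, gb2$table$p)
  expect_equal(nrow(gb1$table), 15)
  expect_named(gb1$band_flags,
               c("delta", "theta", "alpha", "beta", "gamma"))
})

test_that("clinical interaction analysis recovers the generated SUVR association", {
  co <- simulate_cohort(cohort_spec(n_per_group = 40, seed = 8))$cohort
  res <- clinical_interactions(co, "suvr", group = "MCI",
                               measures = c("coh_alpha", "coh_delta"),
                               n_boot = 200, seed = 1)
  expect_lt(res$r[res$measure == "coh_alpha"], -0.5)
  expect_true(res$significant[res$measure == "coh_alpha"])
  expect_false(res$significant[res$measure == "coh_delta"])
  expect_true(all(c("partial_r", "partial_p") %in% names(res)))
})
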
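test_that("connectivity spec validates couplings and stability", {
  expect_error(connectivity_spec(2, data.frame(from = 1, to = 1, lag = 1,
                                               weight = 0.5)), "distinct")
  expect_error(connectivity_spec(2, data.frame(from = 1, to = 3, lag = 1,
                                               weight = 0.5)), "outside")
  unstable <- connectivity_spec(2, data.frame(from = c(1, 2), to = c(2, 1),
                                              lag = 1, weight = 1.2))
  expect_error(simulate_mvar_sources(unstable, 1000, 256, seed = 1),
               "spectral radius")
})

test_that("uncoupled white source has unit variance; chain matches closed-form lag correlation", {
  spec1 <- connectivity_spec(1)
  x <- simulate_mvar_sources(spec1, 10000, 256, seed = 1)
  expect_lt(abs(var(drop(x)) - 1), 0.1)

  # 1 -> 2 at lag 1, weight 0.5: corr(x1_t, x2_{t+1}) = 0.5/sqrt(1.25)
  spec2 <- connectivity_spec(2, data.frame(from = 1, to = 2, lag = 1,
                                           weight = 0.5))
  y <- simulate_mvar_sources(spec2, 10000, 256, seed = 2)
  n <- ncol(y)
  r <- cor(y[1, -n], y[2, -1])
  expect_gt(r, 0.3)
  expect_lt(abs(r - 0.5 / sqrt(1.25)), 0.05)
})

test_that("simulation is bit-identical given the seed and stationary over time", {
  spec <- connectivity_spec(2, data.frame(from = 1, to = 2, lag = 2,
                                          weight = 0.4),
                            band_center_hz = c(10, NA))
  a <- simulate_mvar_sources(spec, 5000, 256, seed = 9)
  b <- simulate_mvar_sources(spec, 5000, 256, seed = 9)
  expect_identical(a, b)
  # no variance trend: first and last fifth comparable
  v1 <- apply(a[, 1:1000], 1, var)
  v2 <- apply(a[, 4001:5000], 1, var)
  expect_true(all(v2 / v1 < 3 & v2 / v1 > 1 / 3))
})

test_that("generator/estimator loop closure: fit_mvar recovers the coefficients", {
  spec <- connectivity_spec(3, data.frame(from = c(1, 2), to = c(2, 3),
                                          lag = 1, weight = 0.5),
                            band_center_hz = c(10, 10, 10),
                            pole_radius = 0.9)
  x <- simulate_mvar_sources(spec, 10000, 256, seed = 3)
  A_true <- sourceflow:::.spec_coefficients(spec, 256)
  fit <- fit_mvar(x, order = length(A_true))
  for (k in seq_along(A_true))
    expect_lt(max(abs(fit$A[[k]] - A_true[[k]])), 0.1)
})

test_that("scalp projection honors the SNR contract and degenerate inputs", {
  lf <- test_lead_field()
  spec <- connectivity_spec(1, band_center_hz = 10)
  src <- simulate_mvar_sources(spec, 256 * 10, 256, seed = 4)
  expect_error(project_to_scalp(src * 0, matrix(c(0, 0, 45), 1),
                                matrix(c(0, 0, 1), 1), lf, 10),
               "SNR undefined for silent sources")
  expect_error(project_to_scalp(src, matrix(c(0, 0, 45), 1),
                                matrix(c(0, 0, 2), 1), lf, 10),
               "unit vectors")

  # one dipole at a grid node, infinite SNR: scalp pattern proportional to
  # that node's oriented gain column
  node <- 25
  pos <- lf$grid[node, , drop = FALSE]
  ori <- matrix(c(0, 0, 1), 1)
  rec <- project_to_scalp(src, pos, ori, lf, Inf, seed = 1)
  g <- lf$gains[node, , 3]
  cc <- abs(cor(rec$data[, 100], g))
  expect_gt(cc, 0.999999)
  expect_lt(max(abs(colSums(rec$data))), 1e-9 * max(abs(rec$data)))
})

test_that("cohort generator reproduces its spec deterministically", {
  cs <- cohort_spec(seed = 11)
  a <- simulate_cohort(cs)$cohort
  b <- simulate_cohort(cs)$cohort
  expect_identical(a, b)
  expect_equal(nrow(a), 34)
  expect_setequal(unique(a$group), c("HC", "MCI"))
  # positivity flag consistent with the cutoff
  expect_equal(a$amyloid_positive, a$suvr >= 1.265)
  # ordinal coding consistent with the genotype risk order
  lv <- c("E2/E3", "E3/E3", "E3/E4", "E4/E4")
  expect_equal(a$apoe_ordinal, match(a$apoe, lv))
  expect_equal(a$e4_carrier, grepl("E4", a$apoe))
})

test_that("degenerate SUVR variance collapses the distribution", {
  cs <- cohort_spec(suvr_params = list(HC = c(1.24, 0), MCI = c(1.45, 0)),
                    seed = 2)
  co <- simulate_cohort(cs)$cohort
  expect_true(all(co$suvr[co$group == "HC"] == 1.24))
  expect_true(all(co$suvr[co$group == "MCI"] == 1.45))
  expect_length(unique(co$amyloid_positive[co$group == "MCI"]), 1)
})

test_that("cohort spec validation rejects bad frequency tables", {
  expect_error(cohort_spec(apoe_freqs = list(HC = c("E3/E3" = 0.5),
                                             MCI = c("E3/E3" = 1))),
               "sum to 1")
  expect_error(cohort_spec(n_per_group = 1), "at least 2")
})

test_that("full recordings can be synthesized for a cohort subset", {
  lf <- test_lead_field()
  conn <- list(
    HC = connectivity_spec(2, data.frame(from = 1, to = 2, lag = 1,
                                         weight = 0.4),
                           band_center_hz = c(10, 10), pole_radius = 0.9),
    MCI = connectivity_spec(2, data.frame(from = 1, to = 2, lag = 1,
                                          weight = 0.2),
                            band_center_hz = c(10, 10), pole_radius = 0.9))
  out <- simulate_cohort(
    cohort_spec(n_per_group = 2, seed = 3), conn_effect = conn,
    recording_cfg = list(lf = lf, duration_s = 20, fs = 256, snr_db = 10,
                         positions = rbind(c(-30, 0, 30), c(30, 15, 15)),
                         orientations = rbind(c(0, 0, 1), c(1, 0, 0)),
                         n_subjects = 2))
  expect_length(out$recordings, 2)
  expect_s3_class(out$recordings[[1]], "eeg_recording")
  expect_equal(out$recordings[[1]]$fs, 256)
})
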
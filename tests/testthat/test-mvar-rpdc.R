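chain3 <- function() {
  connectivity_spec(3, data.frame(from = c(1, 2), to = c(2, 3), lag = 1,
                                  weight = 0.5))
}

test_that("AIC selects the generating order and null fits stay clean", {
  spec <- connectivity_spec(2, data.frame(from = 1, to = 2, lag = 2,
                                          weight = 0.4),
                            band_center_hz = c(10, 10), pole_radius = 0.9)
  hits <- 0
  for (s in 1:10) {
    x <- simulate_mvar_sources(spec, 10000, 256, seed = s)
    if (fit_mvar(x, max_order = 8)$order == 2) hits <- hits + 1
  }
  expect_gte(hits, 8)

  set.seed(3)
  w <- matrix(rnorm(2 * 8000), 2)
  fw <- fit_mvar(w, max_order = 8)
  expect_lte(fw$order, 2)
  expect_lt(max(abs(fw$A[[1]] - diag(diag(fw$A[[1]])))), 0.05)
})

test_that("univariate fit agrees with Yule-Walker", {
  set.seed(4)
  x <- as.numeric(stats::filter(rnorm(20000), c(0.6, -0.3),
                                method = "recursive"))
  f <- fit_mvar(rbind(x), order = 2)
  yw <- stats::ar.yw(x, order.max = 2, aic = FALSE)
  expect_lt(max(abs(c(f$A[[1]], f$A[[2]]) - yw$ar)), 1e-2)
})

test_that("unstable fits are flagged with a warning", {
  # near-unit-root random walk
  set.seed(5)
  x <- rbind(cumsum(rnorm(3000)), rnorm(3000))
  expect_warning(f <- fit_mvar(x, order = 1), "unstable|radius")
  expect_false(f$stable)
})

test_that("RPDC is invariant under per-source rescaling and monotone in display", {
  x <- simulate_mvar_sources(chain3(), 5000, 256, seed = 6)
  m <- fit_mvar(x, order = 1)
  r <- rpdc_spectrum(m, seq(8, 13, 0.25), 256)
  x2 <- x; x2[2, ] <- 100 * x2[2, ]
  r2 <- rpdc_spectrum(fit_mvar(x2, order = 1), r$freqs, 256)
  expect_lt(max(abs(r$rpdc_raw - r2$rpdc_raw)) /
              max(r$rpdc_raw), 1e-6)
  expect_true(all(r$rpdc_display >= 0 & r$rpdc_display < 1))
  # display mapping preserves the raw ordering
  for (p in c(1, 4)) {
    disp_sorted <- r$rpdc_display[p, order(r$rpdc_raw[p, ])]
    expect_true(all(diff(disp_sorted) >= -1e-12))
  }
  expect_equal(r$rpdc_display, r$rpdc_raw / (1 + r$rpdc_raw))
})

test_that("bootstrap-significant, TRT-validated edges recover the chain direction", {
  hits <- 0
  for (s in 1:5) {
    x <- simulate_mvar_sources(chain3(), 5000, 256, seed = 100 + s)
    res <- connectivity_analysis(x, 256, "alpha", max_order = 6,
                                 n_boot = 200, seed = 200 + s)
    k <- paste(res$pairs$from, res$pairs$to)
    sig <- k[res$boot_sig & res$trt_pass]
    if (all(c("1 2", "2 3") %in% sig) &&
          !any(c("2 1", "3 2") %in% sig)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("bootstrap thresholds reject too few draws", {
  x <- simulate_mvar_sources(chain3(), 2000, 256, seed = 7)
  m <- fit_mvar(x, order = 1)
  expect_error(bootstrap_significance(x, m, seq(8, 13, 0.25), 256,
                                      n_boot = 10), "at least 100")
})

test_that("time-reversal test leaves results untouched when nothing is significant", {
  x <- simulate_mvar_sources(chain3(), 5000, 256, seed = 8)
  m <- fit_mvar(x, order = 1)
  r <- rpdc_spectrum(m, seq(8, 13, 0.25), 256)
  r$boot_sig <- rep(FALSE, nrow(r$pairs))
  r2 <- time_reversal_test(x, r)
  expect_true(all(r2$trt_pass == FALSE))
  expect_equal(r2$band_mean_raw, r$band_mean_raw)
})

test_that("flow summaries aggregate directed band means correctly", {
  x <- simulate_mvar_sources(chain3(), 5000, 256, seed = 9)
  m <- fit_mvar(x, order = 1)
  r <- rpdc_spectrum(m, seq(8, 13, 0.25), 256)
  # constant field
  rc <- r; rc$band_mean <- rep(0.3, nrow(r$pairs))
  fs_ <- flow_summaries(rc)
  expect_true(all(abs(fs_$per_source$outflow - 0.3) < 1e-12))
  expect_equal(fs_$global_mean, 0.3)
  # single directed edge of value v among k pairs
  re <- r; re$band_mean <- rep(0, nrow(r$pairs))
  re$band_mean[1] <- 0.6
  expect_equal(flow_summaries(re)$global_mean, 0.6 / nrow(r$pairs))
  # chain head: outflow exceeds inflow
  fr <- flow_summaries(r)
  head_row <- fr$per_source[fr$per_source$source == 1, ]
  expect_gt(head_row$outflow, head_row$inflow)
})

test_that("edge-list export carries the significance columns", {
  x <- simulate_mvar_sources(chain3(), 5000, 256, seed = 10)
  res <- connectivity_analysis(x, 256, "alpha", max_order = 4,
                               n_boot = 100, seed = 1)
  p <- file.path(tempdir(), "edges.csv")
  export_edge_list(res, p)
  back <- read.csv(p)
  expect_equal(nrow(back), 6)
  expect_true(all(c("from", "to", "raw", "display", "boot_sig",
                    "trt_pass") %in% names(back)))
})
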
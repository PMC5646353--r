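test_that("CSD matrix is Hermitian with the right degenerate-input errors", {
  set.seed(1)
  x <- matrix(rnorm(3 * 256 * 30), 3)
  ep <- segment_epochs(eeg_recording(x, c("a", "b", "c"), 256), 2)
  csd <- csd_matrix(ep, "alpha")
  expect_equal(csd$S, Conj(t(csd$S)))
  expect_true(all(Re(diag(csd$S)) > 0))
  expect_lt(max(abs(Im(diag(csd$S)))), 1e-12)

  flat <- x; flat[2, ] <- 0
  epf <- segment_epochs(eeg_recording(flat, c("a", "b", "c"), 256), 2)
  expect_error(csd_matrix(epf, "alpha"), "b")

  short <- eeg_epochs(ep$windows[1:4], 256, 2, ep$channel_labels)
  expect_error(csd_matrix(short, "alpha"), "8 segments")
})

test_that("channel-level coherence from the CSD behaves at its extremes", {
  set.seed(2)
  s <- rnorm(256 * 300)
  # identical signals: coherence 1
  ep <- segment_epochs(eeg_recording(rbind(s, s), c("a", "b"), 256), 2)
  csd <- suppressWarnings(csd_matrix(ep, "alpha"))
  coh <- Mod(csd$S[1, 2])^2 / (Re(csd$S[1, 1]) * Re(csd$S[2, 2]))
  expect_lt(abs(coh - 1), 1e-6)
  # independent noise, 150 segments: coherence near the 1/n bias level
  ep2 <- segment_epochs(eeg_recording(matrix(rnorm(2 * 256 * 300), 2),
                                      c("a", "b"), 256), 2)
  csd2 <- csd_matrix(ep2, "alpha")
  coh2 <- Mod(csd2$S[1, 2])^2 / (Re(csd2$S[1, 1]) * Re(csd2$S[2, 2]))
  expect_lt(coh2, 0.1)
})

test_that("DICS filter satisfies unit gain at each voxel's oriented lead field", {
  lf <- test_lead_field()
  rec <- noise_recording(seconds = 60, seed = 5)
  ep <- segment_epochs(rec, 2)
  csd <- suppressWarnings(csd_matrix(ep, "alpha"))
  filt <- dics_filter(csd, lf, 0.05)
  for (v in c(1, 50, 120)) {
    l <- drop(lf$gains[v, , ] %*% filt$orientation[v, ])
    expect_equal(sum(filt$weights[v, ] * l), 1, tolerance = 1e-8)
  }
  expect_error(dics_filter(csd, lf, -1), "nonnegative")
})

test_that("single simulated dipole is localized at the power-map argmax", {
  lf <- test_lead_field()
  node <- which.min(colSums((t(lf$grid) - c(30, 15, 15))^2))
  spec <- connectivity_spec(1, band_center_hz = 10)
  for (s in 1:2) {
    src <- simulate_mvar_sources(spec, 256 * 60, 256, seed = s)
    rec <- project_to_scalp(src, lf$grid[node, , drop = FALSE],
                            matrix(c(0, 0, 1), 1), lf, 10, seed = 50 + s)
    ep <- segment_epochs(rec, 2)
    filt <- suppressWarnings(dics_filter(csd_matrix(ep, "alpha"), lf, 0.05))
    d <- sqrt(sum((lf$grid[which.max(filt$power), ] - lf$grid[node, ])^2))
    expect_lte(d, lf$spacing)
  }
})

test_that("coherence map is bounded, exactly 1 at the reference, and peaks at a coupled partner", {
  lf <- test_lead_field()
  spec <- connectivity_spec(2, data.frame(from = 1, to = 2, lag = 3,
                                          weight = 0.5),
                            band_center_hz = c(10, 10))
  src <- simulate_mvar_sources(spec, 256 * 120, 256, seed = 7)
  pos <- rbind(c(-30, 0, 30), c(30, 15, 15))
  rec <- project_to_scalp(src, pos, rbind(c(0, 0, 1), c(1, 0, 0)), lf, 10,
                          seed = 7)
  ep <- segment_epochs(rec, 2)
  csd <- csd_matrix(ep, "alpha")
  filt <- dics_filter(csd, lf, 0.05)
  # reference at the power-map seed, as the iterative search uses it
  ref <- which.max(filt$power)
  cm <- coherence_map(csd, filt, ref)
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(cm[ref], 1)
  # a local maximum of the map sits within one grid step of the partner
  # dipole (the one the seed did not land on)
  d_seed <- sqrt(colSums((t(pos) - lf$grid[ref, ])^2))
  partner <- pos[which.max(d_seed), ]
  d_part <- sqrt(colSums((t(lf$grid) - partner)^2))
  is_locmax <- vapply(seq_along(cm), function(v) {
    nb <- which(colSums((t(lf$grid) - lf$grid[v, ])^2) <=
                  (1.5 * lf$spacing)^2)
    all(cm[nb] <= cm[v])
  }, logical(1))
  expect_true(any(is_locmax & d_part <= lf$spacing + 1e-9))
  expect_error(coherence_map(csd, filt, nrow(lf$grid) + 5), "outside")
})

test_that("surrogate threshold enforces its preconditions and separates signal from null", {
  k <- 4
  filt <- identity_filter(k)
  set.seed(8)
  s <- rnorm(256 * 60)
  x <- rbind(s, s + 0.1 * rnorm(length(s)), matrix(rnorm(2 * length(s)), 2))
  ep <- segment_epochs(eeg_recording(x, paste0("v", 1:k), 256), 2)
  expect_error(surrogate_threshold(ep, "alpha", filt, 1, n_perm = 10),
               "at least 20")
  st <- surrogate_threshold(ep, "alpha", filt, 1, n_perm = 50, seed = 1)
  # near-copy channel clearly exceeds; independent channels do not
  expect_gt(st$observed[2], st$threshold[2])
  expect_lt(st$observed[4], 3 * st$threshold[4])
  # too few subsegments
  short <- segment_epochs(eeg_recording(x[, 1:(256 * 10)],
                                        paste0("v", 1:k), 256), 2)
  expect_error(surrogate_threshold(short, "alpha", filt, 1, n_perm = 50),
               "20 one-second")
})

test_that("iterative search finds the coupled network and flags pure noise", {
  lf <- test_lead_field()
  # coupled pair: seed plus one coherent partner
  spec <- connectivity_spec(2, data.frame(from = 1, to = 2, lag = 3,
                                          weight = 0.5),
                            band_center_hz = c(10, 10))
  src <- simulate_mvar_sources(spec, 256 * 120, 256, seed = 7)
  pos <- rbind(c(-30, 0, 30), c(30, 15, 15))
  rec <- project_to_scalp(src, pos, rbind(c(0, 0, 1), c(1, 0, 0)), lf, 10,
                          seed = 7)
  ss <- find_coherent_sources(segment_epochs(rec, 2), "alpha", lf,
                              max_sources = 2, suppress_mm = 30, seed = 3)
  expect_equal(nrow(ss$sources), 2)
  expect_false(ss$flagged)
  found <- as.matrix(ss$sources[, c("x", "y", "z")])
  d <- apply(found, 1, function(f)
    min(sqrt(colSums((t(pos) - f)^2))))
  expect_true(all(d <= lf$spacing))

  # pure noise: seed only, flagged
  recn <- noise_recording(seconds = 60, seed = 21)
  ssn <- suppressWarnings(
    find_coherent_sources(segment_epochs(recn, 2), "alpha", lf,
                          max_sources = 3, suppress_mm = 30, seed = 4))
  expect_equal(nrow(ssn$sources), 1)
  expect_true(ssn$flagged)
})

test_that("extracted source time courses recover the simulated signal at infinite SNR", {
  lf <- test_lead_field()
  node <- which.min(colSums((t(lf$grid) - c(30, 15, 15))^2))
  spec <- connectivity_spec(1, band_center_hz = 10)
  src <- simulate_mvar_sources(spec, 256 * 30, 256, seed = 9)
  rec <- project_to_scalp(src, lf$grid[node, , drop = FALSE],
                          matrix(c(0, 0, 1), 1), lf, Inf, seed = 1)
  ep <- segment_epochs(rec, 2)
  csd <- suppressWarnings(csd_matrix(ep, "alpha"))  # 15 windows < 60 channels
  filt <- dics_filter(csd, lf, 0.05)
  tc <- extract_source_timecourses(ep, node, filt)
  expect_equal(dim(tc), c(1, ncol(src) - ncol(src) %% 512))
  expect_gt(abs(cor(tc[1, ], src[1, seq_len(ncol(tc))])), 0.99)
  # shape contract with two sources
  tc2 <- extract_source_timecourses(ep, c(node, 1), filt)
  expect_equal(nrow(tc2), 2)
})
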
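# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# coarse lead field on the default head model (15 mm test grid)
test_lead_field <- function(spacing = 15) {
  key <- paste0("lf", spacing)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- compute_lead_field(head_model(),
                                              grid_spacing = spacing)
  .fixture_env[[key]]
}

# white-noise recording with the default montage
noise_recording <- function(seconds = 60, fs = 256, seed = 1) {
  set.seed(seed)
  labs <- default_montage()
  to_average_reference(
    eeg_recording(matrix(rnorm(length(labs) * fs * seconds), length(labs)),
                  labs, fs))
}

# instantaneous mixing of one autocorrelated source into two channels
# (volume-conduction surrogate)
mixed_pair <- function(seed, n = 5000) {
  set.seed(seed)
  z <- as.numeric(stats::filter(rnorm(n + 200), c(1.3, -0.6),
                                method = "recursive"))[-(1:200)]
  rbind(0.8 * z + 0.3 * rnorm(n), 0.5 * z + 0.3 * rnorm(n))
}

# identity "spatial filter" exposing k independent series as voxels, for
# source-level calibration of the surrogate machinery
identity_filter <- function(k, band = "alpha") {
  structure(list(weights = diag(k), orientation = matrix(0, k, 3),
                 power = rep(1, k),
                 band = canonical_bands()[canonical_bands()$name == band, ],
                 reg_frac = 0, grid = matrix(as.numeric(seq_len(3 * k)), k, 3),
                 spacing = 5, channel_labels = paste0("v", seq_len(k))),
            class = "spatial_filter")
}
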
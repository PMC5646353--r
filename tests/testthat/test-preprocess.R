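test_that("recording constructor enforces its invariants", {
  d <- matrix(rnorm(20), 2)
  expect_s3_class(eeg_recording(d, c("a", "b"), 256), "eeg_recording")
  expect_error(eeg_recording(d, c("a", "a"), 256), "unique")
  expect_error(eeg_recording(d, "a", 256), "one channel label")
  d[1, 1] <- NA
  expect_error(eeg_recording(d, c("a", "b"), 256), "NA")
})

test_that("average reference zeroes the per-sample channel mean and is idempotent", {
  r <- eeg_recording(matrix(c(1, 3), 2, 1), c("a", "b"), 256)
  expect_equal(as.numeric(to_average_reference(r)$data), c(-1, 1))

  set.seed(1)
  r60 <- eeg_recording(matrix(rnorm(60 * 100), 60), paste0("c", 1:60), 256)
  ar <- to_average_reference(r60)
  expect_lt(max(abs(colSums(ar$data))), 1e-9)
  expect_equal(to_average_reference(ar)$data, ar$data)

  # removes a channel-common offset exactly
  r_off <- r60
  r_off$data <- sweep(r60$data, 2L, rnorm(100), `+`)
  expect_equal(to_average_reference(r_off)$data, ar$data)

  expect_error(to_average_reference(eeg_recording(matrix(1, 1, 5), "a", 256)),
               "two channels")
})

test_that("band-pass, notch and downsampling meet their contracts", {
  fs <- 1000
  t <- seq(1 / fs, 10, by = 1 / fs)
  x <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 50 * t), rnorm(length(t)))
  rec <- eeg_recording(x, c("a", "b", "c"), fs)
  out <- bandpass_notch_downsample(rec, 0.5, 70, 50, 256)

  expect_equal(out$fs, 256)
  expect_equal(ncol(out$data), floor(length(t) * 256 / 1000))
  # in-band 10 Hz amplitude preserved within 5% (away from edges)
  expect_lt(abs(max(abs(out$data[1, 500:2000])) - 1), 0.05)
  # 50 Hz notch residual below 10%
  expect_lt(max(abs(out$data[2, 500:2000])), 0.1)
  expect_error(bandpass_notch_downsample(rec, 0.5, 130, 50, 256), "Nyquist")
})

test_that("segmentation counts windows by the floor rule", {
  mk <- function(minutes) {
    n <- round(minutes * 60 * 256)
    eeg_recording(matrix(rnorm(2 * n), 2), c("a", "b"), 256)
  }
  expect_length(segment_epochs(mk(5), 2)$windows, 150)
  expect_length(segment_epochs(mk(4.1), 2)$windows, 123)
  short <- eeg_recording(matrix(rnorm(2 * round(1.9 * 256)), 2),
                         c("a", "b"), 256)
  expect_error(segment_epochs(short, 2), "shorter than one window")
  expect_error(segment_epochs(mk(5), 0), "positive")
})

test_that("windows are contiguous cuts of the filtered signal", {
  fs <- 256
  set.seed(2)
  rec <- eeg_recording(matrix(rnorm(3 * fs * 10), 3), c("a", "b", "c"), fs)
  filt <- bandpass_notch_downsample(rec, 1, 40, NULL, fs)
  ep <- segment_epochs(filt, 2)
  for (k in c(1, 3, 5)) {
    expect_equal(ep$windows[[k]],
                 filt$data[, ((k - 1) * 512 + 1):(k * 512)])
  }
})

test_that("artifact mask hook keeps exactly the flagged windows", {
  set.seed(3)
  ep <- segment_epochs(eeg_recording(matrix(rnorm(2 * 256 * 8), 2),
                                     c("a", "b"), 256), 2)
  keep <- c(TRUE, FALSE, TRUE, FALSE)
  masked <- apply_artifact_mask(ep, keep)
  expect_length(masked$windows, 2)
  expect_equal(masked$windows[[2]], ep$windows[[3]])
  expect_error(apply_artifact_mask(ep, c(TRUE, FALSE)), "length")
  expect_error(apply_artifact_mask(ep, rep(FALSE, 4)), "every window")
})

test_that("BrainVision round-trip preserves data and metadata", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(4 * 500), 4), c("Fz", "Cz", "Pz", "Oz"),
                       256)
  base <- file.path(tempdir(), "bv_test")
  write_brainvision(rec, base)
  back <- read_brainvision(paste0(base, ".vhdr"))
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$data, rec$data, tolerance = 1e-6)  # float32 storage
})
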
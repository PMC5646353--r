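#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG recording. Data are stored as a
#' channels x samples matrix in microvolts together with the channel labels
#' (10-20/10-10 names), the sampling rate and the current reference state.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channel_labels character vector of unique channel labels, one per row
#'   of `data`.
#' @param fs sampling rate in Hz.
#' @param reference reference state, `"recorded"` (as acquired) or `"average"`
#'   (common average reference).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, fs,
                          reference = c("recorded", "average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric")
  if (anyNA(data)) stop("recording data must not contain NA")
  if (length(channel_labels) != nrow(data))
    stop("need one channel label per data row")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(
    list(data = data, channel_labels = as.character(channel_labels),
         fs = fs, reference = reference),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s reference)\n",
              nrow(x$data), ncol(x$data), x$fs, x$reference))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Epoched EEG
#'
#' Consecutive non-overlapping fixed-length windows cut from a recording.
#'
#' @param windows list of channels x samples matrices, all the same shape.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds; `window_s * fs` must be a whole
#'   number of samples.
#' @param channel_labels channel labels shared by all windows.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(windows, fs, window_s, channel_labels) {
  if (!length(windows)) stop("need at least one window")
  nspw <- window_s * fs
  if (abs(nspw - round(nspw)) > 1e-8)
    stop("window length times sampling rate must be an integer")
  nspw <- round(nspw)
  ok <- vapply(windows, function(w) is.matrix(w) && ncol(w) == nspw &&
                 nrow(w) == length(channel_labels), logical(1))
  if (!all(ok)) stop("all windows must be channels x (window_s * fs) matrices")
  structure(
    list(windows = windows, fs = fs, window_s = window_s,
         channel_labels = as.character(channel_labels)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d windows of %g s, %d channels @ %g Hz\n",
              length(x$windows), x$window_s, length(x$channel_labels), x$fs))
  invisible(x)
}

#' Band-pass filter, notch filter and downsample a recording
#'
#' Zero-phase (forward-backward) Butterworth filtering followed by polyphase
#' resampling. The pass band is implemented as a cascade of 4th-order high-
#' and low-pass sections (24 dB/oct each, doubled by the forward-backward
#' pass), the notch as a 2nd-order band-stop of +/- 2 Hz around the mains
#' frequency. The low-pass, notch and resampling run at the input rate; the
#' high-pass runs after resampling, where its very low normalized corner
#' frequency is numerically better conditioned.
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi pass-band edges in Hz (`lo < hi < fs_out / 2`).
#' @param notch mains frequency to suppress, in Hz, or `NULL` to skip.
#' @param fs_out output sampling rate in Hz.
#' @return A filtered [eeg_recording()] at `fs_out`; the output length is
#'   `floor(n * fs_out / fs)` samples.
#' @export
bandpass_notch_downsample <- function(rec, lo = 0.5, hi = 70, notch = 50,
                                      fs_out = 256) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(lo < hi)) stop("`lo` must be below `hi`")
  if (hi >= fs_out / 2)
    stop("upper pass-band edge must be below the output Nyquist frequency")
  fs_in <- rec$fs
  x <- rec$data

  filt_rows <- function(m, flt) {
    t(apply(m, 1L, function(ch) as.numeric(signal::filtfilt(flt, ch))))
  }

  bl <- signal::butter(4, hi / (fs_in / 2), type = "low")
  x <- filt_rows(x, bl)
  if (!is.null(notch)) {
    if (notch >= fs_in / 2) stop("notch frequency above input Nyquist")
    bs <- signal::butter(2, c(notch - 2, notch + 2) / (fs_in / 2),
                         type = "stop")
    x <- filt_rows(x, bs)
  }

  if (fs_out != fs_in) {
    # the signal is already band-limited well below the output Nyquist by
    # the low-pass above, so cubic-spline evaluation at the new sample
    # times resamples without passband ripple
    n_in <- ncol(x)
    n_out <- floor(n_in * fs_out / fs_in)
    t_in <- (seq_len(n_in) - 1L) / fs_in
    t_out <- (seq_len(n_out) - 1L) / fs_out
    x <- t(apply(x, 1L, function(ch) {
      stats::spline(t_in, ch, xout = t_out, method = "fmm")$y
    }))
  }

  bh <- signal::butter(4, lo / (fs_out / 2), type = "high")
  x <- filt_rows(x, bh)

  eeg_recording(x, rec$channel_labels, fs_out, reference = rec$reference)
}

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' per-sample channel sum becomes zero. Idempotent.
#'
#' @param rec an [eeg_recording()] with at least two channels.
#' @return The average-referenced [eeg_recording()].
#' @export
to_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L)
    stop("average referencing needs at least two channels")
  d <- sweep(rec$data, 2L, colMeans(rec$data))
  eeg_recording(d, rec$channel_labels, rec$fs, reference = "average")
}

#' Cut a recording into consecutive non-overlapping windows
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds (positive; the trailing remainder
#'   shorter than one window is dropped).
#' @return An [eeg_epochs()] object.
#' @export
segment_epochs <- function(rec, window_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (window_s <= 0) stop("`window_s` must be positive")
  nspw <- round(window_s * rec$fs)
  n_win <- floor(ncol(rec$data) / nspw)
  if (n_win < 1L)
    stop("recording shorter than one window")
  wins <- lapply(seq_len(n_win), function(k) {
    rec$data[, ((k - 1L) * nspw + 1L):(k * nspw), drop = FALSE]
  })
  eeg_epochs(wins, rec$fs, window_s, rec$channel_labels)
}

#' Drop windows flagged as artifacts
#'
#' Pass-through hook for artifact rejection: windows are kept or dropped
#' according to a caller-supplied boolean mask (e.g. from manual inspection
#' done outside this package). No automatic cleaning is performed.
#'
#' @param ep an [eeg_epochs()] object.
#' @param keep logical vector, one entry per window; `TRUE` keeps the window.
#' @return The masked [eeg_epochs()] object.
#' @export
apply_artifact_mask <- function(ep, keep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (length(keep) != length(ep$windows))
    stop("mask length must equal the number of windows")
  if (!any(keep)) stop("mask removes every window")
  eeg_epochs(ep$windows[keep], ep$fs, ep$window_s, ep$channel_labels)
}

# concatenate epoch windows back into a channels x samples matrix
.epochs_matrix <- function(ep) do.call(cbind, ep$windows)
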
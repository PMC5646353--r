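#' Canonical EEG frequency bands
#'
#' delta 1-3 Hz, theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz, gamma 30-49 Hz.
#'
#' @return A data frame with columns `name`, `lo`, `hi` (Hz).
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(1, 4, 8, 14, 30),
    hi = c(3, 7, 13, 30, 49),
    stringsAsFactors = FALSE)
}

#' A single frequency band
#'
#' @param name band name.
#' @param lo,hi band edges in Hz, `lo < hi`.
#' @return A one-row band data frame as in [canonical_bands()].
#' @export
frequency_band <- function(name, lo, hi) {
  if (!(lo < hi)) stop("band edges must satisfy lo < hi")
  data.frame(name = name, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

.get_band <- function(band) {
  if (is.character(band)) {
    cb <- canonical_bands()
    i <- match(band, cb$name)
    if (is.na(i)) stop("unknown band name: ", band)
    return(cb[i, ])
  }
  stopifnot(is.data.frame(band), all(c("lo", "hi") %in% names(band)))
  band[1, ]
}

# 10% cosine-tapered (Tukey) window; `frac` is the total tapered fraction
.tukey_window <- function(n, frac = 0.1) {
  if (frac <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  a <- frac / 2
  lo <- t < a
  hi <- t > 1 - a
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + a) / a)))
  w
}

# per-window tapered, zero-padded one-sided FFT; returns complex
# (channels x freqs) scaled so that |.|^2 is a one-sided PSD in uV^2/Hz
.window_fft <- function(w, fs, taper_frac = 0.1, df = 0.25) {
  n <- ncol(w)
  tap <- .tukey_window(n, taper_frac)
  nfft <- round(fs / df)
  if (nfft < n) stop("frequency resolution finer than the window allows")
  wt <- sweep(w, 2L, tap, `*`)
  pad <- matrix(0, nrow(w), nfft - n)
  X <- t(stats::mvfft(t(cbind(wt, pad))))
  keep <- seq_len(nfft %/% 2 + 1L)
  X <- X[, keep, drop = FALSE]
  # one-sided scaling: 2 / (fs * sum(tap^2)), no doubling at DC/Nyquist
  sc <- sqrt(2 / (fs * sum(tap^2)))
  X <- X * sc
  X[, 1L] <- X[, 1L] / sqrt(2)
  if (nfft %% 2 == 0) X[, length(keep)] <- X[, length(keep)] / sqrt(2)
  attr(X, "freqs") <- (keep - 1L) * df
  X
}

#' Power spectral density of epoched EEG
#'
#' Per-channel periodogram with a 10% cosine taper, zero-padded to a 0.25 Hz
#' grid and averaged across windows (Welch estimate over the non-overlapping
#' epochs).
#'
#' @param ep an [eeg_epochs()] object.
#' @param taper_frac tapered fraction of each window (default 10%).
#' @param df frequency resolution of the output grid in Hz.
#' @return An object of class `spectrum_set`: list with `freqs` (Hz), `psd`
#'   (channels x freqs, uV^2/Hz), `n_windows`, `channel_labels`.
#' @export
power_spectrum <- function(ep, taper_frac = 0.1, df = 0.25) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (!length(ep$windows)) stop("no windows to transform")
  acc <- NULL
  for (w in ep$windows) {
    X <- .window_fft(w, ep$fs, taper_frac, df)
    p <- Mod(X)^2
    acc <- if (is.null(acc)) p else acc + p
  }
  psd <- acc / length(ep$windows)
  structure(
    list(freqs = attr(.window_fft(ep$windows[[1L]], ep$fs, taper_frac, df),
                      "freqs"),
         psd = psd, n_windows = length(ep$windows),
         channel_labels = ep$channel_labels),
    class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d channels, %g-%g Hz @ %g Hz, %d windows\n",
              nrow(x$psd), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_windows))
  invisible(x)
}

#' Mean band power per channel
#'
#' Mean of the PSD bins whose centers lie in `[lo, hi]` (both ends included),
#' i.e. the integrated band area divided by the band width in bins.
#'
#' @param sp a [power_spectrum()] result.
#' @param band a band name or one-row band data frame.
#' @return Named numeric vector of per-channel band power (uV^2).
#' @export
band_power <- function(sp, band) {
  stopifnot(inherits(sp, "spectrum_set"))
  b <- .get_band(band)
  sel <- sp$freqs >= b$lo - 1e-9 & sp$freqs <= b$hi + 1e-9
  if (!any(sel)) stop("band lies outside the frequency grid")
  p <- rowMeans(sp$psd[, sel, drop = FALSE])
  names(p) <- sp$channel_labels
  p
}

#' Individual alpha frequency
#'
#' Frequency of the maximal channel-mean PSD inside the alpha search range.
#' If the spectrum is monotone over the range (the maximum sits on a range
#' edge, so there is no alpha peak) the estimate falls back to 10 Hz with a
#' warning and is flagged.
#'
#' @param sp a [power_spectrum()] result.
#' @param search search range in Hz (default 7-13).
#' @return The IAF in Hz, with attribute `flagged` = TRUE when the fallback
#'   was used.
#' @export
estimate_iaf <- function(sp, search = c(7, 13)) {
  stopifnot(inherits(sp, "spectrum_set"))
  sel <- which(sp$freqs >= search[1] & sp$freqs <= search[2])
  if (length(sel) < 3L) stop("alpha search range outside the frequency grid")
  m <- colMeans(sp$psd[, sel, drop = FALSE])
  i <- which.max(m)
  flat <- diff(range(m)) <= 1e-12 * max(abs(m), 1e-300)
  if (flat || i == 1L || i == length(sel)) {
    warning("no alpha peak inside the search range; falling back to 10 Hz")
    return(structure(10.0, flagged = TRUE))
  }
  structure(sp$freqs[sel[i]], flagged = FALSE)
}

#' IAF-adjusted frequency bands
#'
#' Rescales the canonical band edges to the individual alpha frequency: each
#' canonical edge `e` becomes `(e / 10) * iaf`, i.e. the edges are defined as
#' the canonical percentage of the IAF (10.1 Hz gives delta 1.01-3.03 Hz).
#' Applied to delta, theta and beta; the alpha band itself is anchored the
#' same way when `anchor_alpha = TRUE` (default) and left canonical
#' otherwise; gamma is always canonical.
#'
#' @param iaf individual alpha frequency in Hz, inside `[7, 13]`.
#' @param anchor_alpha whether the alpha band is IAF-anchored too.
#' @return A band data frame as in [canonical_bands()].
#' @export
iaf_adjusted_bands <- function(iaf, anchor_alpha = TRUE) {
  if (!is.numeric(iaf) || length(iaf) != 1L || iaf < 7 || iaf > 13)
    stop("`iaf` must be a single value in [7, 13] Hz")
  b <- canonical_bands()
  adj <- b$name %in% c("delta", "theta", "beta") |
    (anchor_alpha & b$name == "alpha")
  b$lo[adj] <- b$lo[adj] / 10 * iaf
  b$hi[adj] <- b$hi[adj] / 10 * iaf
  b
}

#' Export per-channel band power to CSV
#'
#' @param sp a [power_spectrum()] result.
#' @param bands band data frame (default [canonical_bands()]).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
export_band_power <- function(sp, bands = canonical_bands(), path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(bands)), function(i) {
    p <- band_power(sp, bands[i, ])
    data.frame(band = bands$name[i], channel = names(p), power = unname(p),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
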
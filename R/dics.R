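#' Band-limited cross-spectral density matrix
#'
#' Segment-averaged, band-averaged complex cross-spectra between all channel
#' pairs, using the same 10% cosine taper and zero-padded 0.25 Hz grid as
#' [power_spectrum()]. Hermitian by construction; the diagonal equals the
#' band-mean PSD.
#'
#' @param ep an [eeg_epochs()] object with at least 8 windows.
#' @param band band name or one-row band data frame.
#' @param taper_frac tapered fraction of each window.
#' @param df frequency resolution in Hz.
#' @return An object of class `csd_matrix`: list with `S` (channels x
#'   channels complex, uV^2/Hz), `band`, `n_segments`, `freqs_used`,
#'   `channel_labels`.
#' @export
csd_matrix <- function(ep, band, taper_frac = 0.1, df = 0.25) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (length(ep$windows) < 8L) stop("need at least 8 segments for a CSD")
  v <- apply(.epochs_matrix(ep), 1L, stats::var)
  if (any(v <= 0))
    stop("zero-variance channel(s): ",
         paste(ep$channel_labels[v <= 0], collapse = ", "))
  if (length(ep$windows) < length(ep$channel_labels))
    warning("fewer segments than channels: CSD is rank-deficient, ",
            "regularization required downstream")
  b <- .get_band(band)
  acc <- NULL
  freqs_used <- NULL
  for (w in ep$windows) {
    X <- .window_fft(w, ep$fs, taper_frac, df)
    if (is.null(freqs_used)) {
      fr <- attr(X, "freqs")
      sel <- which(fr >= b$lo - 1e-9 & fr <= b$hi + 1e-9)
      if (!length(sel)) stop("band lies outside the frequency grid")
      freqs_used <- fr[sel]
    }
    Xb <- X[, sel, drop = FALSE]
    S_w <- Xb %*% Conj(t(Xb)) / length(sel)
    acc <- if (is.null(acc)) S_w else acc + S_w
  }
  S <- acc / length(ep$windows)
  structure(list(S = S, band = b, n_segments = length(ep$windows),
                 freqs_used = freqs_used, channel_labels = ep$channel_labels),
            class = "csd_matrix")
}

#' @export
print.csd_matrix <- function(x, ...) {
  cat(sprintf("<csd_matrix> %d channels, %s band (%g-%g Hz), %d segments\n",
              nrow(x$S), x$band$name, x$band$lo, x$band$hi, x$n_segments))
  invisible(x)
}

# solve for a possibly ill-conditioned small symmetric matrix
.solve_sym <- function(M, tol = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  if (!any(keep)) stop("matrix is numerically zero")
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' DICS spatial filter
#'
#' Per-voxel unit-gain minimum-variance beamformer weights computed from the
#' real part of the band CSD with diagonal (Tikhonov) regularization of
#' `reg_frac` times the mean CSD diagonal. At each voxel the dipole
#' orientation is fixed to the dominant eigenvector of the 3 x 3 source CSD
#' (output-power) matrix of the unconstrained vector beamformer; the scalar
#' weights then satisfy `w' l = 1` exactly for the oriented lead field `l`.
#' No depth normalization is applied: on noise-only data deep voxels show
#' inflated power (unit-gain beamformer bias), which is documented behavior.
#'
#' @param csd a [csd_matrix()].
#' @param lf a [compute_lead_field()] result with matching channels.
#' @param reg_frac regularization as a fraction of the mean CSD diagonal.
#' @return An object of class `spatial_filter`: `weights` (voxels x
#'   channels), `orientation` (voxels x 3), `power` (voxel source power),
#'   plus grid metadata.
#' @export
dics_filter <- function(csd, lf, reg_frac = 0.05) {
  stopifnot(inherits(csd, "csd_matrix"), inherits(lf, "lead_field"))
  if (reg_frac < 0) stop("`reg_frac` must be nonnegative")
  if (nrow(csd$S) != length(lf$channel_labels))
    stop("CSD and lead field channel counts differ")
  Cr <- Re(csd$S)
  lam <- reg_frac * mean(diag(Cr))
  Creg <- Cr + diag(lam, nrow(Cr))
  Ci <- tryCatch(solve(Creg), error = function(e)
    stop("regularized CSD is singular; increase `reg_frac`", call. = FALSE))
  nv <- nrow(lf$grid)
  W <- matrix(0, nv, nrow(Cr))
  ori <- matrix(0, nv, 3L)
  pow <- numeric(nv)
  for (v in seq_len(nv)) {
    L <- lf$gains[v, , ]
    CiL <- Ci %*% L
    T3 <- crossprod(L, CiL)
    W3 <- CiL %*% .solve_sym(T3)                   # unconstrained vector filter
    P3 <- Re(crossprod(W3, csd$S %*% W3))          # 3x3 source CSD
    u <- eigen((P3 + t(P3)) / 2, symmetric = TRUE)$vectors[, 1L]
    l <- drop(L %*% u)
    Cil <- drop(Ci %*% l)
    w <- Cil / sum(l * Cil)
    W[v, ] <- w
    ori[v, ] <- u
    pow[v] <- Re(drop(crossprod(w, csd$S %*% w)))
  }
  structure(list(weights = W, orientation = ori, power = pow,
                 band = csd$band, reg_frac = reg_frac, grid = lf$grid,
                 spacing = lf$spacing, channel_labels = lf$channel_labels),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf("<spatial_filter> %d voxels, %s band, reg_frac %g\n",
              nrow(x$weights), x$band$name, x$reg_frac))
  invisible(x)
}

#' Source-space coherence map relative to a reference voxel
#'
#' Magnitude-squared coherence between the beamformed source signal at the
#' reference voxel and every other voxel, computed from the band CSD through
#' the spatial-filter weights. The value at the reference voxel is 1.
#'
#' @param csd the [csd_matrix()] the filter was built from.
#' @param filt a [dics_filter()] result.
#' @param ref_voxel reference grid index.
#' @return Numeric vector of per-voxel coherence in \[0, 1\].
#' @export
coherence_map <- function(csd, filt, ref_voxel) {
  stopifnot(inherits(csd, "csd_matrix"), inherits(filt, "spatial_filter"))
  nv <- nrow(filt$weights)
  if (!(ref_voxel %in% seq_len(nv)))
    stop("reference voxel is outside the source grid")
  WS <- filt$weights %*% csd$S                       # voxels x channels
  p_v <- Re(rowSums(WS * filt$weights))
  w_ref <- filt$weights[ref_voxel, ]
  cross <- drop(WS %*% w_ref)
  coh <- Mod(cross)^2 / (p_v * p_v[ref_voxel])
  pmin(pmax(coh, 0), 1)
}

# cut epochs into 1-s subsegments and return tapered band FFTs:
# list(ref = K x F matrix for the reference voxel, vox = K x F x V array)
.subsegment_spectra <- function(ep, band, filt, voxels, seg_s = 1) {
  fs <- ep$fs
  nseg_per_win <- floor(ep$window_s / seg_s)
  if (nseg_per_win < 1L) stop("windows shorter than one subsegment")
  nsp <- round(seg_s * fs)
  b <- .get_band(band)
  X <- .epochs_matrix(ep)
  src <- filt$weights[voxels, , drop = FALSE] %*% X   # V x T
  nwin <- length(ep$windows)
  wlen <- round(ep$window_s * fs)
  segs <- list()
  for (w in seq_len(nwin)) {
    for (s in seq_len(nseg_per_win)) {
      off <- (w - 1L) * wlen + (s - 1L) * nsp
      segs[[length(segs) + 1L]] <- off
    }
  }
  K <- length(segs)
  tap <- .tukey_window(nsp, 0.1)
  nfft <- nsp                                        # native 1/seg_s Hz grid
  fr <- (seq_len(nfft %/% 2 + 1L) - 1L) * fs / nfft
  sel <- which(fr >= b$lo - 1e-9 & fr <= b$hi + 1e-9)
  if (!length(sel)) stop("band outside subsegment frequency grid")
  V <- nrow(src)
  out <- array(0i, dim = c(K, length(sel), V))
  for (k in seq_len(K)) {
    seg <- src[, (segs[[k]] + 1L):(segs[[k]] + nsp), drop = FALSE]
    segt <- sweep(seg, 2L, tap, `*`)
    Xf <- t(stats::mvfft(t(segt)))[, sel, drop = FALSE]
    out[k, , ] <- t(Xf)
  }
  list(spectra = out, K = K, n_bins = length(sel))
}

#' Surrogate significance threshold for source coherence
#'
#' Within-recording Monte-Carlo null for the coherence map: the band spectra
#' of 1-s subsegments of the reference source time course are re-paired with
#' the unshifted subsegment spectra of every voxel by random permutation of
#' the segment order (destroying the temporal pairing while preserving each
#' series' spectrum), and the band-averaged coherence recomputed `n_perm`
#' times. The per-voxel threshold is the 99th percentile of the null
#' coherence. The observed coherence is returned from the same estimator so
#' that observed and null values share the segment-count bias.
#'
#' @param ep the [eeg_epochs()] the filter was built from.
#' @param band band name or one-row band data frame.
#' @param filt a [dics_filter()] result.
#' @param ref_voxel reference grid index.
#' @param n_perm number of permutations (at least 20; 100 by default).
#' @param seed optional RNG seed.
#' @param voxels optional subset of voxel indices to evaluate.
#' @return List with `threshold` and `observed` (per-voxel, on the evaluated
#'   subset), `voxels`, `n_perm`.
#' @export
surrogate_threshold <- function(ep, band, filt, ref_voxel, n_perm = 100,
                                seed = NULL, voxels = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(filt, "spatial_filter"))
  if (n_perm < 20) stop("`n_perm` must be at least 20")
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(filt$weights)
  if (!(ref_voxel %in% seq_len(nv)))
    stop("reference voxel is outside the source grid")
  if (is.null(voxels)) voxels <- seq_len(nv)
  vox_all <- unique(c(ref_voxel, voxels))
  sp <- .subsegment_spectra(ep, band, filt, vox_all)
  if (sp$K < 20L) stop("fewer than 20 one-second subsegments")
  ref_i <- match(ref_voxel, vox_all)
  A <- sp$spectra[, , ref_i, drop = FALSE]
  dim(A) <- dim(sp$spectra)[1:2]                    # K x F
  Vn <- length(vox_all)
  KF <- sp$K * sp$n_bins
  Bmat <- matrix(Conj(sp$spectra), nrow = KF)       # (K*F) x V
  p_ref <- sum(Mod(A)^2)
  p_vox <- colSums(Mod(Bmat)^2)
  obs <- Mod(drop(crossprod(as.vector(A), Bmat)))^2 / (p_ref * p_vox)
  null <- matrix(0, n_perm, Vn)
  for (b in seq_len(n_perm)) {
    Ap <- A[sample.int(sp$K), , drop = FALSE]
    null[b, ] <- Mod(drop(crossprod(as.vector(Ap), Bmat)))^2 /
      (p_ref * p_vox)
  }
  # exact finite-sample permutation threshold: ceil((n_perm + 1) * 0.99)-th
  # order statistic of the null draws (the observed value counts as one more
  # exchangeable draw), so the per-voxel level is at most 1%
  k99 <- min(n_perm, ceiling((n_perm + 1) * 0.99))
  thr <- apply(null, 2L, function(v) sort(v)[k99])
  keep <- match(voxels, vox_all)
  list(threshold = thr[keep], observed = obs[keep], voxels = voxels,
       n_perm = n_perm)
}

#' Iterative identification of the coherent-source network
#'
#' Implements the iterative coherent-source search: (1) the grand power
#' maximum of the DICS power map is the seed; (2) a coherence map is computed
#' with respect to the current reference source; (3) the suprathreshold
#' (surrogate-validated) coherence maximum outside already-claimed voxels is
#' accepted as the next source and becomes the new reference; (4) claimed
#' voxels (within `suppress_mm` of accepted sources) are excluded and the
#' loop repeats until no voxel passes the surrogate threshold or the source
#' cap is reached.
#'
#' @param ep an [eeg_epochs()] object.
#' @param band band name or one-row band data frame.
#' @param lf a [compute_lead_field()] result.
#' @param reg_frac beamformer regularization fraction.
#' @param max_sources source cap (default 5).
#' @param suppress_mm suppression radius around accepted sources in mm.
#' @param n_perm surrogate permutations per iteration.
#' @param seed optional RNG seed for the surrogate permutations.
#' @return An object of class `source_set`: data frame `sources` (grid
#'   index, position, orientation, power, coherence to its reference), the
#'   band, and `flagged = TRUE` when no coherent partner of the seed passed
#'   the surrogate threshold.
#' @export
find_coherent_sources <- function(ep, band, lf, reg_frac = 0.05,
                                  max_sources = 5, suppress_mm = 10,
                                  n_perm = 100, seed = NULL) {
  csd <- csd_matrix(ep, band)
  filt <- dics_filter(csd, lf, reg_frac)
  seed_v <- which.max(filt$power)
  src_idx <- seed_v
  src_coh <- 1
  dist_to <- function(v) sqrt(colSums((t(lf$grid) - lf$grid[v, ])^2))
  claimed <- dist_to(seed_v) <= suppress_mm
  ref <- seed_v
  flagged <- FALSE
  it <- 0L
  # local maxima of a map on the grid: voxels not exceeded by any neighbor
  # within 1.5 grid steps (the seed's smooth leakage halo has no local
  # maximum away from the seed, while a genuine coherent area does)
  local_maxima <- function(vals) {
    r2 <- (1.5 * lf$spacing)^2
    vapply(seq_along(vals), function(v) {
      nb <- which(colSums((t(lf$grid) - lf$grid[v, ])^2) <= r2)
      all(vals[nb] <= vals[v])
    }, logical(1))
  }
  repeat {
    if (length(src_idx) >= max_sources) break
    st <- surrogate_threshold(ep, band, filt, ref, n_perm = n_perm,
                              seed = if (is.null(seed)) NULL else seed + it)
    it <- it + 1L
    cand <- which(!claimed & local_maxima(st$observed))
    if (!length(cand)) {
      if (length(src_idx) == 1L) flagged <- TRUE
      break
    }
    best <- cand[which.max(st$observed[cand])]
    if (st$observed[best] <= st$threshold[best]) {
      if (length(src_idx) == 1L) flagged <- TRUE
      break
    }
    src_idx <- c(src_idx, best)
    src_coh <- c(src_coh, st$observed[best])
    claimed <- claimed | dist_to(best) <= suppress_mm
    ref <- best
  }
  sources <- data.frame(
    voxel = src_idx,
    x = lf$grid[src_idx, 1], y = lf$grid[src_idx, 2], z = lf$grid[src_idx, 3],
    ox = filt$orientation[src_idx, 1], oy = filt$orientation[src_idx, 2],
    oz = filt$orientation[src_idx, 3],
    power = filt$power[src_idx],
    coherence = src_coh,
    label = c("seed", if (length(src_idx) > 1L)
      paste0("coh", seq_len(length(src_idx) - 1L))))
  structure(list(sources = sources, band = .get_band(band),
                 flagged = flagged, filter = filt),
            class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat(sprintf("<source_set> %d source(s), %s band%s\n",
              nrow(x$sources), x$band$name,
              if (x$flagged) " [flagged: no coherent partner]" else ""))
  print(x$sources[, c("voxel", "x", "y", "z", "power", "coherence", "label")],
        row.names = FALSE)
  invisible(x)
}

#' Extract beamformed source time courses
#'
#' Applies the per-source spatial-filter weights to the channel data,
#' concatenated over windows.
#'
#' @param ep an [eeg_epochs()] object.
#' @param srcs a [find_coherent_sources()] result (or a vector of grid
#'   indices).
#' @param filt the [dics_filter()] whose weights to use; defaults to the
#'   filter stored in `srcs`.
#' @return sources x samples matrix with attribute `fs`.
#' @export
extract_source_timecourses <- function(ep, srcs, filt = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"))
  idx <- if (inherits(srcs, "source_set")) srcs$sources$voxel else srcs
  if (is.null(filt)) {
    if (!inherits(srcs, "source_set"))
      stop("`filt` is required when `srcs` is an index vector")
    filt <- srcs$filter
  }
  nv <- nrow(filt$weights)
  if (any(!(idx %in% seq_len(nv)))) stop("source index outside the grid")
  out <- filt$weights[idx, , drop = FALSE] %*% .epochs_matrix(ep)
  attr(out, "fs") <- ep$fs
  out
}

#' Serialize a source set to JSON
#'
#' Writes the identified sources (positions, orientations, power, coherence
#' to reference, labels) together with the band definition.
#'
#' @param srcs a [find_coherent_sources()] result.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
export_source_set_json <- function(srcs, path) {
  stopifnot(inherits(srcs, "source_set"))
  jsonlite::write_json(
    list(band = srcs$band, flagged = srcs$flagged, sources = srcs$sources),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Export a source-grid map as a NIfTI volume
#'
#' Writes per-voxel values (power or coherence tomography) onto the regular
#' source grid as a NIfTI image with the grid spacing as voxel size.
#'
#' @param values per-voxel values aligned with `lf$grid`.
#' @param lf the [compute_lead_field()] the values were computed on.
#' @param path output file path (`.nii` / `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_tomography_nifti <- function(values, lf, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI export")
  sp <- lf$spacing
  ax <- lapply(1:3, function(d) sort(unique(lf$grid[, d])))
  dims <- vapply(ax, length, integer(1))
  vol <- array(NA_real_, dim = dims)
  idx <- cbind(match(lf$grid[, 1], ax[[1]]),
               match(lf$grid[, 2], ax[[2]]),
               match(lf$grid[, 3], ax[[3]]))
  vol[idx] <- values
  img <- RNifti::asNifti(vol, pixdim = c(sp, sp, sp))
  RNifti::writeNifti(img, path)
  invisible(path)
}
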
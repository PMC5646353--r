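#' @useDynLib sourceflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# stack coefficient matrices [A_1 ... A_p] side by side
.coef_block <- function(A) do.call(cbind, A)

#' Companion matrix of an MVAR coefficient set
#'
#' @param A list of p coefficient matrices (m x m), lag 1 first.
#' @return The (m p) x (m p) companion matrix.
#' @export
companion_matrix <- function(A) {
  p <- length(A)
  m <- nrow(A[[1L]])
  comp <- matrix(0, m * p, m * p)
  comp[seq_len(m), ] <- .coef_block(A)
  if (p > 1L)
    comp[(m + 1L):(m * p), seq_len(m * (p - 1L))] <- diag(m * (p - 1L))
  comp
}

#' Spectral radius of the companion matrix
#'
#' The MVAR system is (covariance-)stationary iff this is below 1.
#'
#' @param A list of coefficient matrices.
#' @return Largest eigenvalue magnitude.
#' @export
mvar_spectral_radius <- function(A) {
  max(Mod(eigen(companion_matrix(A), only.values = TRUE)$values))
}

#' Fit a multivariate autoregressive model with AIC order selection
#'
#' Least-squares MVAR fit at every candidate order `1..max_order`; the
#' returned model is the fit at the order minimizing
#' `AIC(p) = log det(Sigma_p) + 2 p m^2 / n` (ties broken toward the smaller
#' order). The model stores everything the renormalized-PDC statistic needs:
#' coefficient matrices, innovation covariance, the inverse regressor
#' cross-product (which scales the coefficient covariance), and residuals.
#'
#' @param sig sources x samples signal matrix.
#' @param max_order largest candidate order (default 20).
#' @param order fixed order; when given, skips AIC selection.
#' @return An object of class `mvar_model`.
#' @export
fit_mvar <- function(sig, max_order = 20, order = NULL) {
  sig <- as.matrix(sig)
  m <- nrow(sig)
  n <- ncol(sig)
  if (is.null(order) && n <= 10 * max_order * m)
    stop("need more than 10 * max_order * m samples")
  tx <- t(sig)
  fit_at <- function(p) {
    E <- stats::embed(tx, p + 1L)
    Y <- E[, seq_len(m), drop = FALSE]
    Z <- E[, (m + 1L):(m * (p + 1L)), drop = FALSE]
    ZtZ <- crossprod(Z)
    B <- tryCatch(solve(ZtZ, crossprod(Z, Y)),
                  error = function(e) stop("singular regressor matrix at order ",
                                           p, call. = FALSE))
    res <- Y - Z %*% B
    N <- nrow(Y)
    Sigma_ml <- crossprod(res) / N
    list(B = B, res = res, N = N, Sigma_ml = Sigma_ml, ZtZ = ZtZ, p = p)
  }
  if (is.null(order)) {
    aic <- rep(NA_real_, max_order)
    fits <- vector("list", max_order)
    for (p in seq_len(max_order)) {
      fits[[p]] <- fit_at(p)
      det_s <- det(fits[[p]]$Sigma_ml)
      aic[p] <- log(max(det_s, .Machine$double.xmin)) +
        2 * p * m^2 / fits[[p]]$N
    }
    p_sel <- which.min(aic)
    f <- fits[[p_sel]]
  } else {
    p_sel <- order
    f <- fit_at(order)
    aic <- NULL
  }
  A <- lapply(seq_len(p_sel), function(k) {
    t(f$B[((k - 1L) * m + 1L):(k * m), , drop = FALSE])
  })
  dof <- f$N - m * p_sel
  Sigma <- crossprod(f$res) / max(dof, 1L)
  if (any(diag(Sigma) <= 0)) stop("degenerate innovation covariance")
  radius <- mvar_spectral_radius(A)
  stable <- radius < 1
  if (!stable)
    warning(sprintf("selected MVAR model is unstable (spectral radius %.3f)",
                    radius))
  structure(list(order = p_sel, A = A, Sigma = Sigma,
                 Ginv = solve(f$ZtZ), residuals = f$res,
                 n_samples = n, n_eff = f$N, m = m,
                 aic_curve = aic, stable = stable,
                 spectral_radius = radius),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> m = %d, order = %d, n = %d, spectral radius %.3f%s\n",
              x$m, x$order, x$n_samples, x$spectral_radius,
              if (x$stable) "" else " (UNSTABLE)"))
  invisible(x)
}

#' Simulate from an MVAR coefficient set
#'
#' Runs the MVAR recursion driven by the supplied innovations (zero initial
#' state, optional burn-in discarded from the front).
#'
#' @param A list of coefficient matrices, lag 1 first.
#' @param innovations m x (n + burn_in) innovation matrix.
#' @param burn_in samples discarded from the front.
#' @return m x n signal matrix.
#' @export
mvar_simulate <- function(A, innovations, burn_in = 0L) {
  x <- .mvar_recurse(.coef_block(A), innovations)
  if (burn_in > 0L) x <- x[, -seq_len(burn_in), drop = FALSE]
  x
}
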
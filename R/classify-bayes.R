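#' SVM classification of cognitive state
#'
#' Soft-margin support-vector classification with the study's validation
#' scheme: features are standardized, the capacity constant C is selected by
#' grid search, and validation uses repeated stratified 75/25 train/test
#' splits (10 repetitions by default). The polynomial kernel (gamma 0.25,
#' degree 3) is the default for EEG-derived features; a linear kernel suits
#' scalar clinical features. Reported accuracies are the mean training and
#' test accuracy across splits at the selected C, and the "overall" accuracy
#' of the selected model refitted on the pooled train+test data (which
#' reproduces the conventional ordering train > overall > test).
#'
#' @param features subjects x measures numeric matrix or data frame.
#' @param labels two-level factor (or coercible), one per subject, at least
#'   8 subjects per class.
#' @param kernel `"polynomial"` (default) or `"linear"`.
#' @param C_grid capacity-constant grid (default logarithmic over 1-1000).
#' @param gamma polynomial kernel coefficient (study convention 0.25).
#' @param degree polynomial kernel degree.
#' @param n_splits repetitions of the stratified 75/25 split.
#' @param train_frac training fraction.
#' @param seed RNG seed; identical data and seed give identical reports.
#' @return An object of class `classification_report`.
#' @export
svm_classify <- function(features, labels, kernel = c("polynomial", "linear"),
                         C_grid = 10^seq(0, 3, length.out = 7),
                         gamma = 0.25, degree = 3, n_splits = 10,
                         train_frac = 0.75, seed = 1) {
  kernel <- match.arg(kernel)
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need two classes")
  if (nlevels(y) > 2L) stop("only two-class problems are supported")
  if (min(table(y)) < 8L) stop("need at least 8 subjects per class")
  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (!ncol(X)) stop("no non-constant features left")
  X <- scale(X)

  set.seed(seed)
  splits <- lapply(seq_len(n_splits), function(s) {
    tr <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, max(1L, round(train_frac * length(idx))))
    }))
    sort(tr)
  })

  fit_eval <- function(C, tr) {
    if (length(unique(y[tr])) < 2L) return(c(NA, NA))
    m <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = kernel,
                    cost = C, gamma = gamma, degree = degree, scale = FALSE)
    acc <- function(idx) mean(stats::predict(m, X[idx, , drop = FALSE]) ==
                                y[idx])
    c(acc(tr), acc(setdiff(seq_along(y), tr)))
  }
  perf <- vapply(C_grid, function(C) {
    rowMeans(vapply(splits, function(tr) fit_eval(C, tr), numeric(2)),
             na.rm = TRUE)
  }, numeric(2))
  best <- which.max(perf[2L, ])              # ties: smaller C wins
  C_sel <- C_grid[best]
  final <- e1071::svm(X, y, kernel = kernel, cost = C_sel, gamma = gamma,
                      degree = degree, scale = FALSE)
  overall <- mean(stats::predict(final, X) == y)
  structure(list(kernel = kernel, C = C_sel, gamma = gamma, degree = degree,
                 accuracy_train = 100 * perf[1L, best],
                 accuracy_test = 100 * perf[2L, best],
                 accuracy_overall = 100 * overall,
                 folds = n_splits, seed = seed,
                 n_features = ncol(X)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s kernel, C = %g%s\n", x$kernel, x$C,
              if (x$kernel == "polynomial")
                sprintf(", gamma = %g, degree = %d", x$gamma, x$degree)
              else ""))
  cat(sprintf("  accuracy: train %.1f%%, test %.1f%%, overall %.1f%% (%d splits)\n",
              x$accuracy_train, x$accuracy_test, x$accuracy_overall, x$folds))
  invisible(x)
}

#' Bayesian estimation of two-group separation
#'
#' Robust two-group Bayesian model (Kruschke-style estimation): each group is
#' t-distributed with its own location and scale and a shared normality
#' parameter; priors are broad and data-scaled (location: normal at the
#' pooled mean with 1000x the pooled sd; scale: uniform over pooled sd /1000
#' to x1000; normality: shifted exponential with mean 29). Posterior sampling
#' by MCMC (JAGS, 3 chains); convergence is checked with the
#' Gelman-Rubin diagnostic and the report is flagged when any R-hat exceeds
#' 1.1. The effect-size posterior is
#' `(mu1 - mu2) / sqrt((sigma1^2 + sigma2^2) / 2)`, and `credible_separation`
#' is the percentage of posterior effect-size mass on its dominant side of 0
#' (100 = fully credible group separation, ~50 = none).
#'
#' @param y1,y2 numeric samples (n >= 5 per group).
#' @param n_steps total MCMC sampling steps across chains (study convention
#'   100,000).
#' @param seed RNG seed.
#' @param n_chains number of chains.
#' @return An object of class `bayes_report`: posterior summaries (mean, sd,
#'   95% HDI) for both locations and scales, the normality parameter and the
#'   effect size, plus `credible_separation` (%), `converged`, `n_steps`,
#'   `seed`.
#' @export
best_estimate <- function(y1, y2, n_steps = 100000, seed = 1, n_chains = 3) {
  y1 <- y1[is.finite(y1)]; y2 <- y2[is.finite(y2)]
  if (length(y1) < 5L || length(y2) < 5L) stop("need n >= 5 per group")
  pooled <- c(y1, y2)
  S <- stats::sd(pooled)
  if (S == 0) stop("degenerate data: pooled standard deviation is 0")
  M <- mean(pooled)
  model_txt <- "
  model {
    for (i in 1:n1) { y1[i] ~ dt(mu[1], tau[1], nu) }
    for (i in 1:n2) { y2[i] ~ dt(mu[2], tau[2], nu) }
    for (g in 1:2) {
      mu[g] ~ dnorm(M, prec_mu)
      sigma[g] ~ dunif(S / 1000, S * 1000)
      tau[g] <- pow(sigma[g], -2)
    }
    nu <- nuMinusOne + 1
    nuMinusOne ~ dexp(1 / 29)
  }"
  data <- list(y1 = y1, y2 = y2, n1 = length(y1), n2 = length(y2),
               M = M, S = S, prec_mu = 1 / (1000 * S)^2)
  inits <- lapply(seq_len(n_chains), function(ch) {
    list(mu = c(mean(y1), mean(y2)),
         sigma = c(max(stats::sd(y1), S / 100), max(stats::sd(y2), S / 100)),
         nuMinusOne = 5,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = seed * 100 + ch)
  })
  jm <- rjags::jags.model(textConnection(model_txt), data = data,
                          inits = inits, n.chains = n_chains, quiet = TRUE)
  stats::update(jm, 1000, progress.bar = "none")
  per_chain <- ceiling(n_steps / n_chains)
  samp <- rjags::coda.samples(jm, c("mu", "sigma", "nu"), n.iter = per_chain,
                              progress.bar = "none")
  gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                              multivariate = FALSE), silent = TRUE)
  converged <- !inherits(gd, "try-error") &&
    all(gd$psrf[, 1L] < 1.1, na.rm = TRUE)
  draws <- as.matrix(samp)
  mu1 <- draws[, "mu[1]"]; mu2 <- draws[, "mu[2]"]
  s1 <- draws[, "sigma[1]"]; s2 <- draws[, "sigma[2]"]
  nu <- draws[, "nu"]
  eff <- (mu1 - mu2) / sqrt((s1^2 + s2^2) / 2)
  hdi <- function(v, mass = 0.95) {
    v <- sort(v)
    k <- max(1L, floor(mass * length(v)))
    widths <- v[(k + 1):length(v)] - v[seq_len(length(v) - k)]
    i <- which.min(widths)
    c(v[i], v[i + k])
  }
  summarize <- function(v) c(mean = mean(v), sd = stats::sd(v),
                             hdi_lo = hdi(v)[1], hdi_hi = hdi(v)[2])
  post <- rbind(mu1 = summarize(mu1), mu2 = summarize(mu2),
                sigma1 = summarize(s1), sigma2 = summarize(s2),
                nu = summarize(nu), effect_size = summarize(eff))
  credible_separation <- 100 * max(mean(eff > 0), mean(eff < 0))
  structure(list(posterior = post,
                 credible_separation = credible_separation,
                 converged = converged,
                 n_steps = n_chains * per_chain, seed = seed),
            class = "bayes_report")
}

#' @export
print.bayes_report <- function(x, ...) {
  cat(sprintf("<bayes_report> %d MCMC steps%s\n", x$n_steps,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$posterior, 4))
  cat(sprintf("  credible separation: %.1f%%\n", x$credible_separation))
  invisible(x)
}
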
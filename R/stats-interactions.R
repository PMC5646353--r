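#' Pooled-variance two-sample t test
#'
#' Unpaired two-sample t with pooled variance, accepting either raw samples
#' or the groups' summary statistics (mean, sd, n), as needed when only
#' published summaries are available.
#'
#' @param x,y numeric samples (ignored when `summary` is given).
#' @param summary list with `mean`, `sd`, `n`, each of length 2.
#' @return List with `t`, `p` (two-sided), `df`.
#' @export
two_sample_t <- function(x = NULL, y = NULL, summary = NULL) {
  if (is.null(summary)) {
    if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
    summary <- list(mean = c(mean(x), mean(y)),
                    sd = c(stats::sd(x), stats::sd(y)),
                    n = c(length(x), length(y)))
  }
  m <- summary$mean; s <- summary$sd; n <- summary$n
  stopifnot(length(m) == 2L, length(s) == 2L, length(n) == 2L)
  if (any(n < 2)) stop("need n >= 2 per group")
  sp2 <- ((n[1] - 1) * s[1]^2 + (n[2] - 1) * s[2]^2) / (sum(n) - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  tval <- (m[1] - m[2]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
  df <- sum(n) - 2
  list(t = tval, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction, as conventional for genotype and sex
#' contingency tables.
#'
#' @param tab counts matrix (2 x k).
#' @return List with `chisq`, `p`, `df`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the contingency table")
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_)^2 / exp_)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chisq = stat, p = stats::pchisq(stat, df, lower.tail = FALSE), df = df)
}

#' Friedman two-way analysis of variance by ranks
#'
#' Rank-based repeated-measures test across conditions (columns) within
#' subjects (rows), with the chi-square reference distribution.
#'
#' @param m subjects x conditions matrix.
#' @return List with `statistic`, `p`, `df`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 subjects and 2 conditions")
  if (all(apply(m, 1L, function(r) diff(range(r)) == 0)))
    return(list(statistic = 0, p = 1, df = ncol(m) - 1))
  ft <- stats::friedman.test(m)
  list(statistic = unname(ft$statistic), p = ft$p.value,
       df = unname(ft$parameter))
}

#' Spearman rank correlation
#'
#' Tie-corrected rank correlation with the t approximation for the p value.
#'
#' @param x,y numeric vectors, n >= 4.
#' @return List with `r`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has no rank correlation")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Partial correlation controlling for a covariate
#'
#' Correlation of the residuals of `x` and `y` after regressing each on the
#' covariate. When `method = "spearman"` all three variables are rank
#' transformed first (the convention when the unconditional analysis is a
#' Spearman correlation). If the covariate explains `x` or `y` essentially
#' exactly, the partial correlation is 0 by convention.
#'
#' @param x,y numeric vectors, n >= 5.
#' @param covar nuisance covariate (e.g. age).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `r`, `p`, `n`.
#' @export
partial_corr <- function(x, y, covar, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y, covar)
  x <- x[ok]; y <- y[ok]; covar <- covar[ok]
  n <- length(x)
  if (n < 5L) stop("need n >= 5")
  if (stats::sd(covar) == 0) stop("covariate is constant (collinear)")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); covar <- rank(covar)
  }
  rx <- stats::resid(stats::lm(x ~ covar))
  ry <- stats::resid(stats::lm(y ~ covar))
  tol <- 1e-10
  if (stats::sd(rx) < tol * stats::sd(x) + 1e-300 ||
        stats::sd(ry) < tol * stats::sd(y) + 1e-300)
    return(list(r = 0, p = 1, n = n))
  r <- stats::cor(rx, ry)
  df <- n - 3
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Percentile bootstrap confidence interval
#'
#' Simple case resampling with `n_boot` iterations; the interval is the
#' percentile CI at the requested level, and an effect is flagged
#' significant when the CI excludes 0. Resamples on which the statistic is
#' undefined (NA/error) are redrawn. Deterministic given `seed`.
#'
#' @param statistic_fn function taking a resampled data object and returning
#'   a scalar.
#' @param data data frame or matrix (rows resampled) or vector.
#' @param n_boot bootstrap iterations.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return List with `lo`, `hi`, `significant`, `n_boot`, `estimate`.
#' @export
bootstrap_ci <- function(statistic_fn, data, n_boot = 1000, level = 0.95,
                         seed = 1) {
  nobs <- if (is.null(dim(data))) length(data) else nrow(data)
  if (nobs < 8L) stop("need at least 8 observations")
  set.seed(seed)
  take <- function(idx) {
    if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
  }
  draws <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    val <- NA_real_
    tries <- 0L
    while (!is.finite(val) && tries < 100L) {
      idx <- sample.int(nobs, nobs, replace = TRUE)
      val <- tryCatch(suppressWarnings(statistic_fn(take(idx))),
                      error = function(e) NA_real_)
      tries <- tries + 1L
    }
    if (!is.finite(val)) stop("statistic undefined on repeated resamples")
    if (tries > 1L) redrawn <- redrawn + tries - 1L
    draws[b] <- val
  }
  if (redrawn > 0L)
    message(redrawn, " undefined resample(s) redrawn")
  a <- (1 - level) / 2
  ci <- stats::quantile(draws, c(a, 1 - a), names = FALSE)
  list(lo = ci[1], hi = ci[2], significant = ci[1] > 0 || ci[2] < 0,
       n_boot = n_boot, estimate = statistic_fn(data))
}

#' Bonferroni adjustment
#'
#' @param pvals p values.
#' @param m family size (defaults to `length(pvals)`; must be at least that).
#' @return Adjusted p values `min(1, p * m)`.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (m < length(pvals)) stop("family size smaller than the number of tests")
  pmin(1, pvals * m)
}

#' Kolmogorov-Smirnov normality test with estimated moments
#'
#' Lilliefors-corrected one-sample KS test against a normal with estimated
#' mean and sd (the naive KS with plugged-in moments is anticonservative).
#'
#' @param x numeric sample, n >= 8.
#' @return List with `D`, `p`, `n`.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8L) stop("need n >= 8")
  if (stats::sd(x) == 0) stop("constant input")
  lt <- nortest::lillie.test(x)
  list(D = unname(lt$statistic), p = lt$p.value, n = length(x))
}

#' Group-comparison battery over EEG summary measures
#'
#' Runs the full band x measure comparison table between the two groups of a
#' cohort: pooled two-sample t tests for source power, coherence and RPDC in
#' each of the five canonical bands (15 tests), Bonferroni-adjusted at the
#' stated family size. A band is flagged when any of its three measures
#' survives correction.
#'
#' @param cohort cohort data frame from [simulate_cohort()] (columns
#'   `<measure>_<band>` and `group`).
#' @param alpha familywise significance level.
#' @param m_correction Bonferroni family size (default 15).
#' @return List with `table` (tidy data frame: measure, band, t, p, p_adj,
#'   significant) and `band_flags` (named logical per band).
#' @export
group_battery <- function(cohort, alpha = 0.05, m_correction = 15) {
  gs <- unique(cohort$group)
  if (length(gs) != 2L) stop("need exactly two groups")
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  measures <- c("power", "coh", "rpdc")
  rows <- list()
  for (msr in measures) {
    for (bd in bands) {
      col <- paste0(msr, "_", bd)
      if (!col %in% names(cohort)) stop("missing cohort column: ", col)
      tt <- two_sample_t(cohort[[col]][cohort$group == gs[1]],
                         cohort[[col]][cohort$group == gs[2]])
      rows[[col]] <- data.frame(measure = msr, band = bd,
                                t = tt$t, p = tt$p,
                                stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adj <- bonferroni(tab$p, m_correction)
  tab$significant <- tab$p_adj < alpha
  flags <- vapply(bands, function(bd) any(tab$significant[tab$band == bd]),
                  logical(1))
  list(table = tab, band_flags = flags)
}

#' Clinical-interaction analysis of EEG measures
#'
#' Spearman correlations (and age-controlled partial correlations) between a
#' clinical covariate (SUVR or the ordinal ApoE coding) and each EEG summary
#' measure, with percentile-bootstrap confidence intervals as the
#' multiplicity control (simple sampling, CI excluding 0 = significant).
#'
#' @param cohort cohort data frame.
#' @param clinical column name of the clinical covariate (`"suvr"` or
#'   `"apoe_ordinal"`).
#' @param group restrict to this group label (default `"MCI"`).
#' @param measures EEG summary column names; defaults to all 15
#'   `<measure>_<band>` columns.
#' @param n_boot bootstrap iterations (study convention: 1000).
#' @param partial_age also compute the age-controlled partial correlation.
#' @param seed RNG seed.
#' @return Tidy data frame: measure, r, p, ci_lo, ci_hi, significant, and
#'   (optionally) partial_r, partial_p.
#' @export
clinical_interactions <- function(cohort, clinical = "suvr", group = "MCI",
                                  measures = NULL, n_boot = 1000,
                                  partial_age = TRUE, seed = 1) {
  d <- cohort[cohort$group == group, , drop = FALSE]
  if (is.null(measures)) {
    bands <- c("delta", "theta", "alpha", "beta", "gamma")
    measures <- as.vector(outer(c("power", "coh", "rpdc"), bands,
                                paste, sep = "_"))
  }
  rows <- lapply(seq_along(measures), function(k) {
    msr <- measures[k]
    sp <- spearman(d[[clinical]], d[[msr]])
    ci <- bootstrap_ci(function(dd) {
      suppressWarnings(stats::cor(dd[[1L]], dd[[2L]], method = "spearman"))
    }, data.frame(d[[clinical]], d[[msr]]), n_boot = n_boot,
    seed = seed + k)
    out <- data.frame(measure = msr, r = sp$r, p = sp$p,
                      ci_lo = ci$lo, ci_hi = ci$hi,
                      significant = ci$significant,
                      stringsAsFactors = FALSE)
    if (partial_age) {
      pc <- partial_corr(d[[clinical]], d[[msr]], d$age)
      out$partial_r <- pc$r
      out$partial_p <- pc$p
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
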
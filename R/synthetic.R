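#' Ground-truth connectivity specification
#'
#' Describes a set of coupled band-limited dipole sources as an MVAR system:
#' each source is an oscillatory AR(2) process centered on `band_center_hz`
#' (a white-noise source when `NA`), and directed couplings inject lagged
#' cross-terms with the given weights. The implied MVAR system must be stable
#' (companion spectral radius below 1), which is validated when the system is
#' built at a concrete sampling rate.
#'
#' @param n_sources number of sources.
#' @param coupling data frame with columns `from`, `to`, `lag` (samples) and
#'   `weight` (dimensionless); `from != to`.
#' @param band_center_hz per-source oscillation center frequency in Hz
#'   (`NA` = white source).
#' @param noise_sd innovation standard deviation (scalar or per source).
#' @param pole_radius AR(2) pole radius in (0, 1) controlling the oscillator
#'   bandwidth (closer to 1 = narrower peak).
#' @return An object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(n_sources, coupling = NULL,
                              band_center_hz = rep(NA_real_, n_sources),
                              noise_sd = 1, pole_radius = 0.95) {
  if (n_sources < 1L) stop("need at least one source")
  if (is.null(coupling))
    coupling <- data.frame(from = integer(), to = integer(),
                           lag = integer(), weight = numeric())
  stopifnot(all(c("from", "to", "lag", "weight") %in% names(coupling)))
  if (any(coupling$from == coupling$to))
    stop("couplings must connect distinct sources (`from != to`)")
  if (any(coupling$from > n_sources | coupling$to > n_sources |
            coupling$from < 1 | coupling$to < 1))
    stop("coupling indices outside 1..n_sources")
  if (any(coupling$lag < 1)) stop("coupling lags must be >= 1 sample")
  if (length(band_center_hz) == 1L)
    band_center_hz <- rep(band_center_hz, n_sources)
  if (length(band_center_hz) != n_sources)
    stop("need one band center per source")
  if (!(pole_radius > 0 && pole_radius < 1))
    stop("`pole_radius` must be in (0, 1)")
  noise_sd <- rep_len(noise_sd, n_sources)
  if (any(noise_sd <= 0)) stop("`noise_sd` must be positive")
  structure(list(n_sources = n_sources, coupling = coupling,
                 band_center_hz = band_center_hz, noise_sd = noise_sd,
                 pole_radius = pole_radius),
            class = "connectivity_spec")
}

# realize the spec's MVAR coefficient matrices at a sampling rate
.spec_coefficients <- function(spec, fs, weight_scale = 1) {
  m <- spec$n_sources
  osc <- !is.na(spec$band_center_hz)
  if (any(spec$band_center_hz[osc] >= fs / 2))
    stop("band center at or above the Nyquist frequency")
  p <- max(2L * any(osc), if (nrow(spec$coupling)) max(spec$coupling$lag) else 1L, 1L)
  A <- lapply(seq_len(p), function(k) matrix(0, m, m))
  rho <- spec$pole_radius
  for (s in which(osc)) {
    A[[1L]][s, s] <- 2 * rho * cos(2 * pi * spec$band_center_hz[s] / fs)
    A[[2L]][s, s] <- -rho^2
  }
  cp <- spec$coupling
  for (r in seq_len(nrow(cp))) {
    A[[cp$lag[r]]][cp$to[r], cp$from[r]] <-
      A[[cp$lag[r]]][cp$to[r], cp$from[r]] + cp$weight[r] * weight_scale
  }
  A
}

#' Simulate coupled MVAR dipole source signals
#'
#' Runs the stable MVAR recursion of a [connectivity_spec()] with Gaussian
#' innovations; deterministic given `seed`.
#'
#' @param spec a [connectivity_spec()].
#' @param n_samples samples to return (after burn-in); must exceed 10x the
#'   maximum lag.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed.
#' @param weight_scale multiplier applied to every coupling weight (used by
#'   the cohort generator to modulate coupling strength).
#' @param burn_in leading samples discarded to remove the zero initial state.
#' @return sources x n_samples matrix with attribute `fs`.
#' @export
simulate_mvar_sources <- function(spec, n_samples, fs, seed = 1,
                                  weight_scale = 1, burn_in = 500L) {
  stopifnot(inherits(spec, "connectivity_spec"))
  A <- .spec_coefficients(spec, fs, weight_scale)
  if (n_samples <= 10 * length(A))
    stop("`n_samples` must exceed 10x the maximum lag")
  radius <- mvar_spectral_radius(A)
  if (radius >= 1)
    stop(sprintf("unstable source system: companion spectral radius %.3f >= 1",
                 radius))
  set.seed(seed)
  m <- spec$n_sources
  innov <- matrix(stats::rnorm((n_samples + burn_in) * m, sd = spec$noise_sd),
                  nrow = m)
  x <- mvar_simulate(A, innov, burn_in = burn_in)
  attr(x, "fs") <- fs
  x
}

#' Project source signals to the scalp through the forward model
#'
#' Places each source signal on a dipole (position + fixed orientation),
#' evaluates the five-shell forward solution for a nominal 10 nA*m moment,
#' sums the scalp contributions and adds white Gaussian sensor noise,
#' uncorrelated across channels, at the requested signal-to-noise ratio
#' (mean per-channel signal variance over noise variance, in dB). The result
#' is average-referenced.
#'
#' @param sources sources x samples matrix (e.g. from
#'   [simulate_mvar_sources()]).
#' @param dipole_positions sources x 3 matrix, mm, inside the gray-matter
#'   shell.
#' @param dipole_orientations sources x 3 matrix of unit orientation vectors.
#' @param lf a [compute_lead_field()] result (supplies head model and
#'   electrode layout).
#' @param sensor_noise_snr SNR in dB; `Inf` for noise-free.
#' @param seed RNG seed for the sensor noise.
#' @param fs sampling rate stored in the output recording; defaults to the
#'   `fs` attribute of `sources`.
#' @return An [eeg_recording()] in microvolts, average-referenced.
#' @export
project_to_scalp <- function(sources, dipole_positions, dipole_orientations,
                             lf, sensor_noise_snr = 10, seed = 1, fs = NULL) {
  stopifnot(inherits(lf, "lead_field"))
  sources <- as.matrix(sources)
  if (is.null(fs)) fs <- attr(sources, "fs")
  if (is.null(fs)) stop("supply `fs` (not stored on `sources`)")
  dipole_positions <- rbind(dipole_positions)
  dipole_orientations <- rbind(dipole_orientations)
  if (nrow(dipole_positions) != nrow(sources) ||
        nrow(dipole_orientations) != nrow(sources))
    stop("need one dipole position and orientation per source")
  onorm <- sqrt(rowSums(dipole_orientations^2))
  if (any(abs(onorm - 1) > 1e-6))
    stop("dipole orientations must be unit vectors")
  if (all(abs(sources) < .Machine$double.eps))
    stop("SNR undefined for silent sources")
  moment <- 10e-9                                   # nominal dipole, A*m
  G <- forward_potentials(lf, dipole_positions,
                          dipole_orientations * moment) * 1e6   # uV
  Y <- G %*% sources
  if (is.finite(sensor_noise_snr)) {
    sig_var <- mean(apply(Y, 1L, stats::var))
    noise_var <- sig_var / 10^(sensor_noise_snr / 10)
    set.seed(seed)
    Y <- Y + matrix(stats::rnorm(length(Y), sd = sqrt(noise_var)),
                    nrow = nrow(Y))
  }
  rec <- eeg_recording(Y, lf$channel_labels, fs, reference = "recorded")
  to_average_reference(rec)
}

#' Cohort specification
#'
#' Group structure and clinical-covariate distributions for the synthetic
#' cohort generator. Defaults emulate a two-group resting-state study of
#' healthy controls (HC) and mild cognitive impairment (MCI): n = 17 per
#' group, global amyloid burden (PiB SUVR) normal with HC 1.24 (0.2) and MCI
#' 1.45 (0.2), amyloid positivity at SUVR >= 1.265, apolipoprotein-E
#' genotype frequencies matching the study's genotyping (HC dichotomous
#' 13 E3/E3 + 4 E3/E4; MCI 1 E2/E3, 11 E3/E3, 4 E3/E4, 1 E4/E4), and a
#' negative rank correlation between SUVR and band-limited connectivity in
#' the impaired group.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param suvr_params named list of `c(mean, sd)` per group, SUVR units.
#' @param apoe_freqs named list of per-group genotype frequency tables
#'   (must sum to 1 within each group).
#' @param suvr_connectivity_r target Spearman correlation between SUVR and
#'   mean connectivity in the impaired group.
#' @param suvr_cutoff amyloid-positivity threshold, SUVR units.
#' @param seed RNG seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 17,
                        suvr_params = list(HC = c(1.24, 0.2),
                                           MCI = c(1.45, 0.2)),
                        apoe_freqs = list(
                          HC = c("E3/E3" = 13 / 17, "E3/E4" = 4 / 17),
                          MCI = c("E2/E3" = 1 / 17, "E3/E3" = 11 / 17,
                                  "E3/E4" = 4 / 17, "E4/E4" = 1 / 17)),
                        suvr_connectivity_r = -0.8,
                        suvr_cutoff = 1.265,
                        seed = 1) {
  if (n_per_group < 2L) stop("need at least 2 subjects per group")
  stopifnot(identical(sort(names(suvr_params)), sort(names(apoe_freqs))))
  for (g in names(apoe_freqs)) {
    if (abs(sum(apoe_freqs[[g]]) - 1) > 1e-8)
      stop("genotype frequencies must sum to 1 in group ", g)
    if (any(apoe_freqs[[g]] < 0)) stop("negative genotype frequency")
  }
  if (abs(suvr_connectivity_r) >= 1)
    stop("target rank correlation must be inside (-1, 1)")
  structure(list(n_per_group = n_per_group, suvr_params = suvr_params,
                 apoe_freqs = apoe_freqs,
                 suvr_connectivity_r = suvr_connectivity_r,
                 suvr_cutoff = suvr_cutoff, seed = seed),
            class = "cohort_spec")
}

# ApoE genotype risk ordering and the e4-carrier flag
.apoe_ordinal <- function(genotype) {
  lv <- c("E2/E3", "E3/E3", "E3/E4", "E4/E4")
  o <- match(genotype, lv)
  if (anyNA(o)) stop("unknown ApoE genotype: ",
                     paste(unique(genotype[is.na(o)]), collapse = ", "))
  o
}

# per-group EEG summary distributions: list(measure -> band -> c(mean, sd)).
# Alpha and beta carry the study's (significant) group differences; the
# other bands share a common across-group mean so that they are genuinely
# null in the generator's ground truth. Dispersions follow the study's
# group-difference table.
.default_eeg_summaries <- function() {
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  mk <- function(mean, sd) Map(c, mean, sd)
  list(
    HC = list(
      coh = stats::setNames(mk(c(0.195, 0.165, 0.19, 0.17, 0.095),
                               c(0.03, 0.025, 0.03, 0.02, 0.02)), bands),
      power = stats::setNames(mk(c(1.255, 1.15, 1.37, 1.52, 0.87),
                                 c(0.04, 0.05, 0.06, 0.09, 0.14)), bands),
      rpdc = stats::setNames(mk(c(0.175, 0.165, 0.21, 0.25, 0.13),
                                c(0.03, 0.035, 0.03, 0.02, 0.025)), bands)),
    MCI = list(
      coh = stats::setNames(mk(c(0.195, 0.165, 0.14, 0.13, 0.095),
                               c(0.03, 0.025, 0.03, 0.03, 0.02)), bands),
      power = stats::setNames(mk(c(1.255, 1.15, 0.98, 0.89, 0.87),
                                 c(0.04, 0.05, 0.07, 0.17, 0.14)), bands),
      rpdc = stats::setNames(mk(c(0.175, 0.165, 0.15, 0.19, 0.13),
                                c(0.03, 0.035, 0.02, 0.03, 0.025)), bands)))
}

#' Simulate a two-group cohort with known ground truth
#'
#' Draws per-subject clinical covariates (age, sex, education, MMSE, CERAD
#' z, PiB SUVR, ApoE genotype with ordinal risk coding and e4-carrier flag)
#' and per-subject EEG summary measures (band power, coherence, RPDC per
#' frequency band) from the group distributions of the [cohort_spec()]. In
#' the impaired group a latent per-subject connectivity factor is coupled to
#' the SUVR normal score through a Gaussian copula (Pearson correlation
#' `2 sin(pi * r_s / 6)` on the latent scale for target Spearman `r_s`), so
#' that the realized rank correlation between SUVR and mean alpha-band
#' connectivity matches the spec's negative target; the same factor
#' multiplies the ground-truth coupling weights (`exp(0.25 * z)`) when full
#' recordings are synthesized. Deterministic given the spec's seed.
#'
#' @param cspec a [cohort_spec()].
#' @param conn_effect optional named list of per-group [connectivity_spec()]s
#'   used when recordings are generated.
#' @param recording_cfg optional list enabling full EEG synthesis per
#'   subject: `lf` (lead field), `positions`, `orientations`, `duration_s`,
#'   `fs`, `snr_db`, and optionally `n_subjects` to limit how many subjects
#'   get a recording.
#' @return List with `cohort` (data frame, one row per subject; EEG summary
#'   columns named `<measure>_<band>`, plus `mean_connectivity` and
#'   `coupling_multiplier`) and `recordings` (named list of
#'   [eeg_recording()]s, empty unless `recording_cfg` is given).
#' @export
simulate_cohort <- function(cspec, conn_effect = NULL, recording_cfg = NULL) {
  stopifnot(inherits(cspec, "cohort_spec"))
  set.seed(cspec$seed)
  groups <- names(cspec$suvr_params)
  n <- cspec$n_per_group
  demo <- list(
    HC = list(age = c(71.8, 4.6), mmse = c(29.65, 0.6),
              cerad = c(0.75, 1.2), edu = c(15.35, 2.7), p_male = 13 / 17),
    MCI = list(age = c(72.1, 4.6), mmse = c(28.41, 1.4),
               cerad = c(-0.95, 1.1), edu = c(14.76, 2.9), p_male = 13 / 17))
  eeg_def <- .default_eeg_summaries()
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  rho <- 2 * sin(pi * cspec$suvr_connectivity_r / 6)

  rows <- list()
  for (g in groups) {
    sp <- cspec$suvr_params[[g]]
    dm <- if (g %in% names(demo)) demo[[g]] else demo[[1L]]
    z_suvr <- stats::rnorm(n)
    suvr <- sp[1] + sp[2] * z_suvr
    impaired <- g == "MCI" || g == groups[length(groups)]
    z_conn <- if (impaired && sp[2] > 0) {
      rho * z_suvr + sqrt(1 - rho^2) * stats::rnorm(n)
    } else stats::rnorm(n)
    fr <- cspec$apoe_freqs[[g]]
    geno <- sample(names(fr), n, replace = TRUE, prob = fr)
    df <- data.frame(
      id = sprintf("%s%02d", g, seq_len(n)),
      group = g,
      age = stats::rnorm(n, dm$age[1], dm$age[2]),
      sex = ifelse(stats::runif(n) < dm$p_male, "M", "F"),
      education = stats::rnorm(n, dm$edu[1], dm$edu[2]),
      mmse = pmin(30, round(stats::rnorm(n, dm$mmse[1], dm$mmse[2]), 1)),
      cerad_z = stats::rnorm(n, dm$cerad[1], dm$cerad[2]),
      suvr = suvr,
      amyloid_positive = suvr >= cspec$suvr_cutoff,
      apoe = geno,
      apoe_ordinal = .apoe_ordinal(geno),
      e4_carrier = grepl("E4", geno),
      coupling_multiplier = exp(0.25 * z_conn),
      stringsAsFactors = FALSE)
    es <- if (g %in% names(eeg_def)) eeg_def[[g]] else
      eeg_def[[if (impaired) "MCI" else "HC"]]
    for (msr in c("power", "coh", "rpdc")) {
      for (bd in bands) {
        ms <- es[[msr]][[bd]]
        tied <- impaired && bd == "alpha" && msr %in% c("coh", "rpdc")
        z <- if (tied) z_conn else stats::rnorm(n)
        df[[paste0(msr, "_", bd)]] <- ms[1] + ms[2] * z
      }
    }
    df$mean_connectivity <- (df$coh_alpha + df$rpdc_alpha) / 2
    rows[[g]] <- df
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL

  recordings <- list()
  if (!is.null(recording_cfg)) {
    cfg <- recording_cfg
    stopifnot(inherits(cfg$lf, "lead_field"))
    n_rec <- min(nrow(cohort), cfg$n_subjects %||% nrow(cohort))
    for (k in seq_len(n_rec)) {
      gk <- cohort$group[k]
      spec_k <- if (!is.null(conn_effect)) conn_effect[[gk]] else
        stop("`conn_effect` is required to synthesize recordings")
      src <- simulate_mvar_sources(
        spec_k, n_samples = round(cfg$duration_s * cfg$fs), fs = cfg$fs,
        seed = cspec$seed * 1000L + k,
        weight_scale = cohort$coupling_multiplier[k])
      recordings[[cohort$id[k]]] <- project_to_scalp(
        src, cfg$positions, cfg$orientations, cfg$lf,
        sensor_noise_snr = cfg$snr_db %||% 10,
        seed = cspec$seed * 1000L + k, fs = cfg$fs)
    }
  }
  list(cohort = cohort, recordings = recordings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort table to CSV
#'
#' Column dictionary: `id`, `group`; demographics `age` (years), `sex`,
#' `education` (years), `mmse` (0-30), `cerad_z` (z score); amyloid burden
#' `suvr` (PiB SUVR), `amyloid_positive` (SUVR >= cutoff); genetics `apoe`
#' (genotype), `apoe_ordinal` (risk rank E2/E3 < E3/E3 < E3/E4 < E4/E4),
#' `e4_carrier`; EEG summaries `<measure>_<band>` for measure in power
#' (log source power), coh (source coherence), rpdc (directed coherence) and
#' the five canonical bands; `mean_connectivity` (mean of alpha coherence
#' and alpha RPDC); `coupling_multiplier` (ground-truth coupling scale).
#'
#' @param cohort the cohort data frame from [simulate_cohort()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
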
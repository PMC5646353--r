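# sourceflow

Source-space analysis of resting-state EEG for two-group clinical studies:
band-limited spectral power, functional coupling (coherence) and directed
information flow between cortical sources, and their interactions with
clinical risk markers such as cortical amyloid burden (PiB-PET SUVR) and
ApoE ε4 genotype. The package targets the kind of study that compares
healthy controls (HC) with participants with mild cognitive impairment
(MCI) from eyes-closed resting EEG, and ships a synthetic-cohort generator
so the entire chain is testable against known ground truth without any
patient data.

## What it computes

- **Spectral power** per channel and band (delta 1–3, theta 4–7, alpha
  8–13, beta 14–30, gamma 30–49 Hz) from 2-s windows on a 0.25 Hz grid,
  with individual-alpha-frequency (IAF) band adjustment: each canonical
  edge *e* is rescaled to (*e*/10)·IAF, so an IAF of 10.1 Hz gives a delta
  band of 1.01–3.03 Hz.
- **DICS beamforming** (dynamic imaging of coherent sources): a
  minimum-variance spatial filter built from the band-limited complex
  cross-spectral density matrix **S**(f) on a five-concentric-sphere
  analytic head model, with per-voxel weights
  *w* = C⁻¹ℓ / (ℓᵀC⁻¹ℓ) (unit gain at the voxel, C = Re **S** +
  regularization), mapping source power and source coherence onto a regular
  grid and iteratively identifying the coherent-source network with a
  within-recording permutation (surrogate) threshold.
- **Renormalized partial directed coherence (RPDC)**: the source signals
  extracted by the beamformer are modelled as a multivariate autoregressive
  (MVAR) process (least squares, AIC order selection); for each directed
  pair j→i the statistic λ_{j→i}(f) is the quadratic form of
  (Re, Im) Ā_ij(f) in its inverse estimator covariance — nonnegative,
  scale-invariant, ~χ²(2) under no coupling. Significance is assessed by a
  residual-resampling bootstrap (95th percentile, family-corrected) and
  validated by time-reversal testing (TRT), which rejects connections whose
  asymmetry does not flip on time-reversed signals (volume conduction).
- **Group statistics**: pooled t tests (also from published summary
  statistics), χ², Friedman, tie-corrected Spearman and age-controlled
  partial correlations, percentile-bootstrap confidence intervals,
  Bonferroni correction, Lilliefors normality testing, and a 15-test
  band × measure group battery.
- **Classification and Bayesian estimation**: SVM classification of
  cognitive state (polynomial kernel, gamma 0.25, repeated stratified 75/25
  validation, C by grid search) and a robust Bayesian two-group model
  (t-distributed groups, MCMC) reporting the posterior effect size
  (μ₁−μ₂)/√((σ₁²+σ₂²)/2) and the credible separation between groups.
- **Synthetic cohorts**: coupled band-limited MVAR dipole sources projected
  through the forward model, plus clinical covariates (SUVR, ApoE, MMSE,
  CERAD, demographics) with a Gaussian-copula SUVR–connectivity link in the
  impaired group.

## Worked example

Simulate a study-sized cohort (17 HC, 17 MCI) and run the group battery,
the clinical interaction, the classifier and the Bayesian separation:

```r
library(sourceflow)

co <- simulate_cohort(cohort_spec(seed = 42))$cohort

gb <- group_battery(co)          # 15 pooled t tests, Bonferroni m = 15
gb$band_flags
#> delta theta alpha  beta gamma
#> FALSE FALSE  TRUE  TRUE FALSE

mci <- co[co$group == "MCI", ]
spearman(mci$suvr, mci$coh_alpha)
#> alpha coherence vs SUVR (MCI): r = -0.91, p < 1e-4

feats <- as.matrix(co[, grep("^(power|coh|rpdc)_", names(co))])
svm_classify(feats, co$group, seed = 1)
#> <classification_report> polynomial kernel, C = 1, gamma = 0.25, degree = 3
#>   accuracy: train 100.0%, test 100.0%, overall 100.0% (10 splits)

best_estimate(co$power_alpha[co$group == "HC"],
              co$power_alpha[co$group == "MCI"],
              n_steps = 20000, seed = 1)
#> <bayes_report> 20001 MCMC steps
#>                mean      sd hdi_lo  hdi_hi
#> mu1          1.3656  0.0130 1.3397  1.3908
#> mu2          0.9663  0.0193 0.9269  1.0037
#> ...
#> effect_size  6.3869  1.0451 4.4170  8.5172
#>   credible separation: 100.0%
```

The battery flags exactly the bands that carry group effects in the
generator (alpha and beta); alpha coherence is negatively rank-correlated
with amyloid burden in the impaired group as generated; the EEG feature set
separates the groups completely at this effect size, and the Bayesian model
confirms 100% credible separation for alpha power.

The full signal chain — recordings, beamforming, directed connectivity —
runs the same way from synthetic dipoles:

```r
lf   <- compute_lead_field(head_model(), grid_spacing = 15)
spec <- connectivity_spec(2, data.frame(from = 1, to = 2, lag = 3,
                                        weight = 0.5),
                          band_center_hz = c(10, 10))
src  <- simulate_mvar_sources(spec, 256 * 120, fs = 256, seed = 7)
rec  <- project_to_scalp(src, rbind(c(-30, 0, 30), c(30, 15, 15)),
                         rbind(c(0, 0, 1), c(1, 0, 0)), lf,
                         sensor_noise_snr = 10, seed = 7)
net  <- find_coherent_sources(segment_epochs(rec, 2), "alpha", lf,
                              max_sources = 2, suppress_mm = 30, seed = 3)
tc   <- extract_source_timecourses(segment_epochs(rec, 2), net)
connectivity_analysis(tc, 256, "alpha", n_boot = 400, seed = 1)
```

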
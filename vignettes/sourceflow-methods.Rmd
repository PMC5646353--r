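---
title: "Source-space EEG power, coherence and directed connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space EEG power, coherence and directed connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`sourceflow` implements a complete resting-state EEG analysis chain for
two-group source-connectivity studies — the kind of study that asks whether
band-limited oscillatory power, functional coupling (coherence) and directed
information flow between cortical sources differ between healthy controls
(HC) and participants with mild cognitive impairment (MCI), and whether those
EEG measures relate to clinical risk markers such as cortical amyloid burden
(PiB-PET SUVR) and ApoE ε4 genotype. This vignette describes the models, the
parameters that matter, the numerical choices, and what the synthetic-cohort
tests do and do not establish about real data.

## Pipeline overview

1. **Preprocessing** (`bandpass_notch_downsample`, `to_average_reference`,
   `segment_epochs`): zero-phase Butterworth band-pass (0.5–70 Hz, 4th order
   = 24 dB/oct per pass direction), 50 Hz notch, resampling to 256 Hz,
   common-average reference, segmentation into non-overlapping 2-s windows.
2. **Spectra** (`power_spectrum`, `band_power`, `estimate_iaf`,
   `iaf_adjusted_bands`): tapered FFT per window averaged across windows on a
   0.25 Hz grid; band power in the canonical bands delta 1–3, theta 4–7,
   alpha 8–13, beta 14–30, gamma 30–49 Hz; individual-alpha-frequency (IAF)
   band adjustment.
3. **Forward model** (`head_model`, `compute_lead_field`): analytic
   five-concentric-sphere volume conductor (white matter, gray matter, CSF,
   skull, skin) with a regular source grid.
4. **DICS beamforming** (`csd_matrix`, `dics_filter`, `coherence_map`,
   `surrogate_threshold`, `find_coherent_sources`,
   `extract_source_timecourses`): frequency-domain minimum-variance
   beamformer mapping band power and source coherence onto the grid, with an
   iterative, surrogate-thresholded search for the coherent-source network.
5. **Directed connectivity** (`fit_mvar`, `rpdc_spectrum`,
   `bootstrap_significance`, `time_reversal_test`, `flow_summaries`):
   multivariate autoregressive (MVAR) modelling of the extracted source
   signals, renormalized partial directed coherence (RPDC), bootstrap
   significance and time-reversal validation.
6. **Group statistics** (`two_sample_t`, `spearman`, `partial_corr`,
   `bootstrap_ci`, `group_battery`, `clinical_interactions`): group
   comparisons with Bonferroni control and clinical-covariate interaction
   analyses with bootstrap confidence intervals.
7. **Classification and Bayesian estimation** (`svm_classify`,
   `best_estimate`): SVM classification of cognitive state from EEG
   summaries, and a robust Bayesian two-group model quantifying credible
   group separation.
8. **Synthetic cohorts** (`connectivity_spec`, `simulate_mvar_sources`,
   `project_to_scalp`, `cohort_spec`, `simulate_cohort`): ground-truth
   generator exercising every stage.

## Preprocessing choices

The pass band is implemented as separate 4th-order high- and low-pass
Butterworth sections applied forward-backward (`signal::filtfilt`), giving
zero phase — essential for connectivity work — and an effective 48 dB/oct
rolloff; the attenuation one octave outside the pass band therefore exceeds
20 dB by a wide margin. The notch is a 2nd-order band-stop at ±2 Hz around
the mains frequency. Resampling is done by cubic-spline evaluation at the new
sample times *after* the anti-alias low-pass: with the signal band-limited to
70 Hz and input rates of 500–1000 Hz, the spline interpolation error is below
0.1% while polyphase FIR resamplers of moderate order show percent-level
passband ripple. The high-pass runs after resampling, where its normalized
corner frequency is larger and the filter numerically better conditioned.
Windows are non-overlapping 2-s blocks; the trailing remainder is dropped.
Artifact handling is a pass-through mask (`apply_artifact_mask`): synthetic
data are clean, and manual or ICA cleaning of real data happens upstream.

## Spectral estimation

Each 2-s window is tapered with a 10% cosine-taper (Tukey) window — the
convention in commercial EEG analyzers, where a "Hanning window: 10%" means
10% of the window length is tapered — and zero-padded from 512 to 1024
samples so that the 2-s windows yield the 0.25 Hz grid (the native resolution
of a 2-s window is 0.5 Hz; zero-padding is the only way to reconcile the two
figures). PSD scaling is one-sided, `2 / (fs * sum(w^2))`, which makes the
integrated PSD match the signal variance (verified by a white-noise Parseval
test to within 10%).

Band power is the mean of the PSD bins whose centers fall inside the closed
band interval — the integrated band area divided by the band width in bins.
When several bands are summarized jointly, a bin on a shared edge belongs to
the lower band (determinism).

The IAF is the frequency of the maximal channel-mean PSD in 7–13 Hz. If the
spectrum is monotone over the search range (maximum on a range edge — no
alpha peak), the estimate falls back to 10 Hz with a warning and a flag;
fixed-band results are unaffected. IAF-adjusted bands scale each canonical
band edge `e` to `(e/10) * IAF`, i.e. the edges are held at a fixed
percentage of the IAF: at IAF 10.1 Hz the delta band becomes 1.01–3.03 Hz.
Whether the alpha band itself is IAF-anchored is configurable
(`anchor_alpha`, default `TRUE`); gamma is always canonical.

## The five-shell forward model

The volume conductor is five concentric spheres. Default radii are 63, 72,
78, 85, 88 mm (white matter, gray matter, CSF, skull, skin) with
conductivities 0.14, 0.33, 1.79, 0.01, 0.43 S/m — conventional published
shell values scaled to an 88-mm scalp; they are configuration, not a fidelity
claim about any individual head, and every value is stored in the
`head_model` object. Electrode positions are an idealized 10-10 template
built geometrically (great-circle interpolation between each coronal row's
midline position and its end point on the 10% circumferential ring,
extrapolated one step for the 9/10 positions); the template ships as a TSV
and is explicitly synthetic.

The potential of a dipole at radius `b` is expanded in Legendre series; per
degree the five-shell boundary-value problem is solved with 2×2 interface
transfer matrices and an outer Neumann condition. Two numerical points
matter. First, all radii are normalized by the scalp radius so the powers
`b^(n-1)` decay. Second, the per-degree responses are differences of terms
carrying radius-ratio powers `~a^(2n+1)`; beyond some degree the computed
values hit the double-precision noise floor and then grow spuriously, while
the true responses decay geometrically (inner-image reflections) or level
off (transmission). The solver detects the noise takeover (loss of smooth
decay) and continues the tail geometrically from the last trusted terms.
With the default 80 terms, the series truncation error is below 1e-9
relative everywhere on the source grid, and at equal conductivities the
solution matches the classical single-sphere closed-form series to machine
precision (an independent derivation used as the test oracle). The source
grid is masked to the gray-matter radius minus one grid step, where
beamformer weights are well behaved; the exact center is excluded
(orientation-degenerate).

## DICS beamforming

The band CSD matrix is the segment- and bin-averaged complex cross-spectrum
using the same taper and grid as the PSD. The spatial filter at each voxel
minimizes output variance subject to unit gain, computed from the real part
of the CSD plus `reg_frac` (default 0.05) times the mean diagonal as
regularization. The dipole orientation is fixed per voxel as the dominant
eigenvector of the 3×3 source CSD of the unconstrained vector beamformer.
No depth normalization is applied: on noise-only data, deep voxels show
inflated power (the classic unit-gain center-of-head bias). This is
documented behavior; localization tests use signals with 10 dB SNR, where
the bias is irrelevant (the acceptance suite requires at least 90% of 50
single-dipole localizations within one grid step).

Source coherence relative to a reference voxel is the magnitude-squared
band-averaged cross-spectrum between the beamformed source signals,
normalized by their powers; it is 1 at the reference by construction.

**Surrogate significance.** The within-recording null re-pairs 1-s
subsegments of the reference source time course with the unshifted voxel
subsegments by random permutation — destroying the temporal pairing while
preserving each series' spectrum (permuting both jointly would preserve the
coupling and give no null). The per-voxel threshold is the exact
permutation-test order statistic `ceil((n_perm+1) * 0.99)` of the null
draws, so the per-voxel level is at most 1%; the observed coherence is
computed with the same subsegment estimator so observed and null share the
segment-count bias. Calibration on independent source series gives an
empirical false-positive rate of ~1.2% (bound: twice nominal).

**What the surrogate does and does not control.** The surrogate tests
temporal dependence. Beamformer *leakage* — one source bleeding into the
weights of surrounding voxels — is a genuine dependence present at any SNR,
and a calibrated test will detect it. The iterative source search therefore
(a) claims voxels within `suppress_mm` (default 10 mm, two grid steps at the
5-mm production spacing) of accepted sources, and (b) only accepts
*local maxima* of the coherence map: the leakage halo of an accepted source
decays smoothly and has no local maximum away from its peak, while a genuine
coherent area does. Residual spurious secondary lobes can survive in
adverse geometries; the directed-connectivity stage (bootstrap + time
reversal) is the final arbiter of which connections are real. The source cap
(default 5 per band) matches the largest network size the emulated study
reports.

## MVAR and renormalized partial directed coherence

Source signals are modelled as a joint MVAR process fitted by least squares,
with the order selected by minimizing
`AIC(p) = log det(Sigma_p) + 2 p m^2 / n` over `1..max_order` (ties toward
the smaller order; default cap 20 at 256 Hz). The renormalized PDC statistic
for a directed pair j→i at frequency f is the quadratic form of
`(Re, Im)` of the transfer-polynomial entry `A̅_ij(f)` in the inverse of its
estimator covariance (derived from the innovation covariance and the inverse
regressor cross-product). It is nonnegative, approximately chi-square(2)
under no coupling, and invariant under rescaling of any source signal
(verified to 1e-6). At order 1 the real and imaginary parts are collinear
and the covariance is rank-1; the implementation switches to the closed-form
pseudo-inverse quadratic form in that case. The raw statistic is unbounded;
for display and for group summaries it is mapped monotonically into [0, 1)
as `λ/(1+λ)`, and both scales are serialized.

**Bootstrap significance.** The null for pair j→i simulates the fitted
model with that coupling zeroed, driven by resampled residual rows
(preserving innovation cross-covariance), refits at the same order and
records the band-mean statistic; the threshold is the 95th percentile.
`connectivity_analysis` additionally divides the error rate by the number of
directed pairs tested (Bonferroni family correction), consistent with the
emulated study's across-the-board multiple-comparison correction; the
uncorrected single-pair threshold remains available
(`bootstrap_significance(..., family_size = 1)`). The bootstrap chain is
implemented in compiled code; 400 draws per pair on a 3-source, 5000-sample
problem take about a second.

**Time-reversal testing (TRT).** Connections passing the bootstrap are
validated by refitting on time-reversed signals: pair j→i keeps
`trt_pass = TRUE` only if its net asymmetry `λ(j→i) − λ(i→j)` is positive on
the original signals *and* negative after reversal. Genuinely lagged
interactions flip; instantaneous mixtures (volume conduction) do not (the
acceptance suite requires rejection in at least 90% of 50 seeds). Two caveats are worth
recording. First, the reversed fit mirrors *noise* asymmetries too, so TRT
does not filter bootstrap false positives — that is what the family
correction above is for. Second, narrowband oscillators coupled at very
short lags are quasi-instantaneous (a one-sample lag at 10 Hz and 256 Hz is
a 14° phase shift), and the reversal flip degrades; TRT is intentionally
conservative in that regime. The decision rule is isolated in
`time_reversal_test` so alternative rules from the literature can be swapped
in.

## Group statistics

`two_sample_t` is the pooled-variance unpaired t test and accepts published
summary statistics directly — the MMSE worked example (29.65 ± 0.6 vs
28.41 ± 1.4, n = 17 each) reproduces t = 3.4. `chi_square` is Pearson's test
without continuity correction. `friedman_test` wraps the rank-based
two-way analysis of variance. `spearman` is tie-corrected; `partial_corr`
correlates residuals after regressing both variables on the covariate and
rank-transforms first when the primary analysis is Spearman (the convention
when correlating with ordinal ApoE risk and non-normal amyloid burden; the
choice is logged per analysis by the `method` argument). If the covariate
explains a variable essentially exactly, the partial correlation is 0 by
convention. `bootstrap_ci` implements percentile intervals from simple case
resampling (study convention: 1000 iterations), with an effect flagged
significant when the CI excludes zero; undefined resamples are redrawn and
reported. `ks_normality` is the Lilliefors-corrected KS test (naive KS with
estimated moments is anticonservative). `group_battery` runs the 15-test
band × measure comparison with Bonferroni m = 15 and reports per-band flags
(a band is flagged when any of its three measures survives correction);
family sizes for the clinical-interaction (30) and cognition (36) analyses
are arguments, not constants.

## Classification and Bayesian separation

`svm_classify` standardizes features, drops constants with a warning, and
selects the capacity constant C by grid search (default logarithmic 1–1000 —
the wider of the two ranges the emulated study mentions; the chosen C is
reported). Validation is by repeated stratified 75/25 train/test splits (10
repetitions), the reading we adopt of a "10-fold validation by taking 75%
for training and 25% for testing"; the polynomial kernel uses gamma 0.25 and
degree 3 (degree unstated in the study; configurable). "Overall" accuracy is
defined as the accuracy of the selected model refitted on the pooled
train+test data — a definition choice, stated prominently because it is what
makes the conventional ordering train > overall > test reproducible. No
Weibull pre-test is implemented for clinical features: the linear kernel is
selected by the caller. Permuted-label data classify at chance for every
kernel (leakage guard in the test suite).

`best_estimate` is a robust Bayesian two-group model: each group
t-distributed with its own location and scale, a shared normality parameter
ν (shifted-exponential prior, mean 29), broad data-scaled priors (location:
normal at the pooled mean with 1000× pooled SD; scale: uniform over pooled
SD / 1000 to × 1000), sampled with JAGS in 3 chains and checked with the
Gelman–Rubin diagnostic (flagged if any R̂ > 1.1). The effect-size posterior
is `(μ1−μ2)/sqrt((σ1²+σ2²)/2)`; `credible_separation` is the percentage of
posterior effect-size mass on its dominant side of zero, which is ~50–60%
for indistinguishable groups and ≈100% for a d = 2 effect at n = 17.

## The synthetic cohort: what it emulates, and what tests on it show

`simulate_cohort` emulates the study conditions: two groups of 17; PiB SUVR
normal with HC 1.24 (0.2) and MCI 1.45 (0.2) and positivity at ≥ 1.265;
ApoE genotype frequencies matching the study's genotyping (HC 13 E3/E3 +
4 E3/E4; MCI 1 E2/E3, 11 E3/E3, 4 E3/E4, 1 E4/E4) with the ordinal risk
coding ε2/ε3 < ε3/ε3 < ε3/ε4 < ε4/ε4 and the ε4-carrier flag; demographics
(age ~72 ± 4.6, 13 M/5 F, MMSE 29.65 ± 0.6 vs 28.41 ± 1.4, CERAD z 0.75 ±
1.2 vs −0.95 ± 1.1) matching the study's cohort table.

Per-subject EEG summaries (power, coherence, RPDC × 5 bands) are drawn from
group distributions in which **alpha and beta carry the group effects** at
the magnitudes of the study's group-difference table, while delta, theta and
gamma share a common across-group mean — so the generator's null bands are
genuinely null and "flags exactly the effect-carrying bands" is a
well-posed property. The SUVR–connectivity association in the impaired
group is a Gaussian copula: a latent connectivity factor with latent-scale
correlation `2 sin(π r_s / 6)` to the SUVR normal score yields the target
Spearman `r_s` (default −0.8); the same factor multiplies the ground-truth
MVAR coupling weights (`exp(0.25 z)`) when full recordings are synthesized
through the forward model. Sensor noise is white and uncorrelated across
channels — the simplest model consistent with the beamformer's assumptions;
correlated noise would require a config extension.

What passing tests on this cohort establish: the estimators recover the
quantities the generator planted (localization to one grid step at 10 dB
SNR, directed-edge sets, rank correlations to ±0.1, battery flags) at the
study's sample sizes. What they do not establish: robustness to realistic
artifacts (eye blinks, muscle), correlated sensor noise, anatomical head
geometry (the spheres are not a BEM), inter-subject forward-model
variability, or narrowband regimes where TRT is conservative (above).
Simulation and inversion also share the same spherical forward model — an
"inverse crime" that makes localization easier than on real heads.

## Problem sizes in the validation suite

The test and acceptance runs use deliberately scaled problem sizes chosen to
exercise every code path at meaningful statistical power: a 15-mm source
grid (250 voxels, 60 channels) for beamformer tests, 5000-sample 3-source
MVAR chains with 400 bootstrap draws × 100 seeds for direction recovery,
200-repetition calibration runs for the surrogate (per-voxel level 1%) and
bootstrap (per-pair level 5%) nulls, 50-cohort batteries, and 20,000 MCMC
steps for the Bayesian model (the production default is 100,000). The 5-mm
grid of a production analysis is a drop-in change of `grid_spacing`.

## Known limitations

- Spherical head model only; no BEM/FEM, no individual anatomy.
- The iterative source search can accept secondary leakage lobes in adverse
  two-source geometries; inspect `coherence` values and rely on the directed
  stage for final network claims.
- EDF reading is not implemented (BrainVision is the supported interchange
  format); lead fields serialize to RDS.
- No multitaper or wavelet spectra; no time-varying MVAR; no DTF or
  transfer-entropy variants.
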
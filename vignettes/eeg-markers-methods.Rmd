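---
title: "Computational EEG markers for seizure-recurrence prognosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational EEG markers for seizure-recurrence prognosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whether a patient who undergoes a routine scalp EEG will have a seizure in the
following year is the question the treating neurologist actually cares about,
yet visual EEG reading answers it only indirectly: interictal epileptiform
discharges (IEDs) are specific but insensitive, and most routine EEGs show
none. `eegprog` implements a quantitative pipeline for this prognosis problem:
it extracts ten linear and non-linear signal markers from annotated routine
EEG recordings, trains classifiers for one-year seizure recurrence under
patient-grouped nested cross-validation, and runs the clinical follow-up
analyses (subgroup performance, per-marker comparison, two-step combination
with IEDs, and time-to-event modelling). Because clinical EEG archives cannot
be redistributed, the package ships a synthetic-cohort generator with known
ground truth; every stage of the pipeline is validated against it.

## Signal model and preprocessing

Recordings are 19-channel, 10–20 system, 200 Hz EDF files with technologist
annotations (montage changes, hyperventilation, photic stimulation, eye
opening/closure). Preprocessing follows standard clinical-quantitative
practice:

* **Filtering.** Zero-phase Hamming-window FIR filters: high-pass at 0.75 Hz
  (transition bandwidth 0.75 Hz) and a 2 Hz-wide notch at 60 Hz. A single-pass
  linear-phase filter with group-delay compensation gives an exactly
  zero-phase response for the symmetric designs used here.
* **Referencing.** Common average reference; all downstream analysis assumes
  it.
* **Epoching.** Ten-second epochs cut at annotation-driven time points: every
  montage change, every 15 s during hyperventilation, every 15 s for the
  2 min after it, every photic-stimulation frequency, and every eye event.
  Epochs that would overrun the recording are skipped.
* **Artifact handling.** For each recording, a per-channel peak-to-peak
  rejection threshold is selected by five-fold cross-validation: candidate
  thresholds (40 log-spaced values between the 10th and 99.9th percentile of
  that channel's observed peak-to-peak amplitudes) are scored by the RMSE
  between the mean of retained training epochs and the pointwise median of
  validation epochs, and the smallest minimizer is kept. This is a
  deliberately simplified, fully reproducible variant of cross-validated
  amplitude rejection; the published Bayesian-optimization machinery of the
  full method is out of scope. Channel-epochs above threshold are re-estimated
  by Perrin-style spherical-spline interpolation (order-4 Legendre expansion,
  50 terms, regularization 1e-5) on the unit-sphere 10–20 positions; epochs
  with more than 30% bad channels are dropped. The 0.3 cap bounds the
  interpolation error; interpolation is per-epoch, matching the per-
  epoch/channel threshold semantics.

## The ten markers

Band power (BP) and peak alpha frequency (PAF) are computed on the raw
epoch-channel series; the other eight are computed on each of six sym5
discrete-wavelet detail levels (at 200 Hz: 100–50, 50–25, 25–12.5, 12.5–6.25,
6.25–3.125, 3.125–1.56 Hz), giving 59 values per channel per epoch.

* **BP**: DPSS multitaper PSD (time-bandwidth 4, 7 tapers) integrated by
  Simpson's rule over ten bands (low/high delta, theta, alpha, beta, gamma;
  1–100 Hz), reported as log10 power with a floor of 1e-12 uV^2. The floor
  turns degenerate flat channels into a well-defined constant instead of
  -Inf. A band-pass-filtered variant is provided; the multitaper integral is
  the default.
* **PAF**: frequency of the multitaper-PSD maximum in 8–13 Hz after FIR
  band-pass filtering; exact ties resolve to the lower frequency, and noise
  without an alpha peak still returns the argmax (flagging low-prominence
  peaks is left to the caller).
* **Hurst exponent**: rescaled-range slope over log-spaced windows from 10
  samples to half the series.
* **Line length**: sum of absolute successive differences.
* **Correlation dimension**: Grassberger–Procaccia slope of the correlation
  sum over 20 log-spaced radii between the 5th and 50th percentile of pairwise
  embedded distances. The fixed percentile scaling region trades a little
  bias for exact reproducibility across series. For long series the
  correlation sum uses an evenly strided subset of at most 500 templates,
  which bounds the quadratic pairwise cost without materially changing the
  slope.
* **Entropies**: approximate (Pincus, self-matches), sample
  (Richman–Moorman, no self-matches), fuzzy (baseline-removed templates,
  membership `exp(-(d/r)^n)`), permutation (ordinal patterns normalized by
  `log(k!)`), and spectral (normalized Shannon entropy of the multitaper
  PSD). Shared parameters `m = 3`, `r = 0.25` (fraction of the series SD),
  `tau = 5`, `n = 2`, `k = 3`; the single delay `tau` applies to all embedded
  estimators and to the correlation dimension. Degenerate (constant) series
  return 0 by convention — all templates match, a single ordinal pattern —
  rather than propagating NaN; series shorter than the embedding are flagged
  missing.

Parameter selection for the entropies maximizes the ratio of between-recording
variance to mean within-recording variance on calibration recordings
(`select_entropy_params()`); since no clinical calibration EEGs can ship with
the package, the function is exercised on synthetic recordings and the
defaults above are used throughout.

Missing marker values (degenerate or too-short level series) are imputed by
chained ridge regressions: column means as initialization, kernel-form ridge
(`lambda = 1e-3`) per incomplete column, iterated to a 1e-3 maximum cell
change or 10 sweeps. Imputation statistics are always fitted on the training
split and applied to held-out rows.

## Evaluation design

Each epoch is one learning observation; all statistics are computed at the
EEG level after aggregating epoch scores with the empirical median (any
quantile from 0.1 to 0.9 is supported). Four classifiers are evaluated —
L1/L2-regularized logistic regression (glmnet), an RBF-kernel SVM (e1071),
a random forest (ranger), and gradient-boosted trees (xgboost, configured
with leaf-wise growth like LightGBM). Feature selection is an L1-penalized
linear SVM (squared hinge, FISTA proximal gradient, written in-package since
no pre-installed R library provides one); columns with nonzero coefficients
survive, and an empty selection falls back to all columns.

Nested cross-validation uses five patient-grouped outer folds and ten
patient-grouped inner folds; the inner loop picks the selection strength and
hyperparameters by pooled per-EEG aggregated AUC. Outer-fold AUCs are averaged
and a confidence interval is computed from the influence function of the
cross-validated AUC (LeDell-style); the temporally shifted holdout instead
uses the DeLong variance on single per-EEG predictions. Patient leakage is
structurally impossible (folds are assigned per patient) and additionally
audited in tests. Classes are reweighted by inverse prevalence by default;
standardization, imputation and selection are always fitted inside the
training portion of whatever split is being evaluated. The default
hyperparameter grids are small on purpose (the inner loop multiplies
everything by its fold count); they are ordinary, field-standard settings,
not tuned values. p-values against chance come from a one-sample z-test of
the CV-AUC against 0.5 on the influence-function variance, unadjusted (a
Bonferroni switch is available to callers that make many comparisons).

Model variants mirror clinical usage: age interactions (standardized age and
age-by-feature products appended to the feature set), and two-step rules
where a positive clinical flag (IEDs, focal lesion) forces a positive
prediction and the model scores only flag-negative EEGs.

## Post-hoc analyses

Subgroup AUCs (age group, sex, lesion, IED status, slowing, ASM count,
epilepsy type) are recomputed within strata using the existing fold
assignment; strata with fewer than five EEGs in either class are reported as
not estimable — an explicit, reproducible cutoff standing in for "too small
to estimate". Per-marker comparisons re-run the nested CV per marker family
with the fold assignment injected, so every marker sees identical splits.
Predicted risk is dichotomized at the cohort mean (strictly above = high; a
median switch exists because "above average" is ambiguous). The survival
analysis fits a Cox proportional-hazards model (Efron ties) of the risk group
controlled for standardized age, sex, and ASM count (continuous), checks
proportionality with the scaled-residual trend test, and falls back to a
ridge-penalized refit under separation; Kaplan–Meier curves carry Greenwood
95% bands, a log-rank test, and the 52-week survival per group.

## The synthetic cohort generator

The generator emulates exactly the statistical structure the analysis
exploits, nothing more. Per patient: a one-year recurrence label drawn at the
configured prevalence (default 0.24, the scale seen in routine-EEG cohorts),
a latent risk `y + N(0, 0.2)` coupling signal effects to survival, clinical
covariates with class-dependent frequencies on the scale of published
routine-EEG cohorts, and one recording. Each channel is pink (1/f) noise plus
a narrowband alpha oscillator (Gaussian spectral bump of 0.25 Hz width
centered at a configurable population mean, default 10.5 Hz with 0.2 Hz
between-recording jitter, posterior-weighted) plus a broadband AR(1)/white-
noise mixture. Class effects enter through the latent risk: the alpha
log-power shift and the broadband mixing-logit shift are standardized effect
sizes, the alpha peak-frequency shift is in Hz (default effects 0.5, 0.3 and
−0.5 respectively — moderate, consistent with the modest AUCs such cohorts
support). The narrow oscillator and the tight latent-risk noise are
calibration choices that make a configured standardized shift express itself
in the corresponding marker at close to its nominal size, which the
effect-recovery checks require. IED-like events (70 ms triangular
spike + 300 ms half-sine wave, 3x background SD, focally weighted over the
four nearest electrodes) are inserted at class-dependent rates, and
high-amplitude boxcar artifacts (10x SD, 0.5–2 s, 1–3 channels) exercise the
rejection path. The default annotation schedule compresses the clinical
protocol into 300 s: montage changes every 150 s, hyperventilation at 60 s
for 90 s, ten photic frequencies (4–22 Hz) of 10 s, eye events every 60 s.
Activation *responses* (photic driving, hyperventilation slowing) are not
modelled; annotations exist to drive the epoching logic. Follow-up is uniform
on 26–156 weeks, matching the interquartile scale of reported follow-up.

Survival needs one reconciliation: the cohort draws labels at a configured
prevalence *and* event times from an exponential model with hazard
`lambda * exp(beta * risk)`. Both cannot hold marginally at once, so
`simulate_cohort()` draws the label first and samples the event/censoring
times from the exponential model conditionally on it (truncated draws); the
standalone `simulate_outcomes()` keeps the unconditional exponential
generator, which is what the survival-recovery validations use.

What passing tests on this generator do **not** show: robustness to real
artifact diversity (muscle, electrode pop, sweat), volume-conduction spatial
structure, sleep architecture, non-stationarity over a 20–60 min recording,
or the true effect sizes of clinical EEG — the generator's effects are
planted, so recovery demonstrates the pipeline's correctness, not clinical
performance.

## Numerical choices and problem sizes

* DPSS tapers come from the symmetric tridiagonal eigenproblem and are cached
  per length; the sym5 filter pair is hard-coded and the periodized transform
  is exactly orthogonal for lengths divisible by `2^levels` (odd-length
  levels pad by repeating the last sample, so energy-conservation checks use
  a divisible length).
* Fuzzy-entropy memberships below `exp(-30)` are treated as zero; this is far
  below the 1e-10 oracle-equivalence tolerance.
* The validation suite scales the study down to what a laptop-class run
  completes in minutes, sizes chosen once as the package's own validation
  conditions: effect-recovery and null-calibration cohorts use 60 patients
  with three 10-s epochs per recording at the full 19 channels and
  artifact-free signal (the artifact/repair path has its own dedicated
  checks); the per-marker ranking repeats use constructed cohort-shaped
  feature matrices (50 patients, two epochs, the full channel-by-marker
  column layout, patient-grouped folds) with a 1.5-SD shift planted in the
  band-power family only, across 10 seeds; coverage simulations use 200 EEGs
  and 500 replicates; survival recovery uses 500 patients and 200
  replicates. The ranking check is constructed at the feature level because
  a signal-level injection cannot be marker-exclusive: the ten markers are
  coupled descriptions of the same oscillatory signal. An amplitude effect
  co-moves line length (an amplitude surrogate) and spectral entropy; a
  peak-frequency shift co-moves log band powers whenever the oscillator sits
  within the multitaper bandwidth of a band edge (the log of the smoothed
  spectral tail is a sensitive frequency detector), and co-moves the
  wavelet-level entropies and line length through the level's effective
  sampling rate. Sensitivity maps of the level-4 markers against oscillator
  frequency show no placement that silences all nine competitors at once, so
  marker-exclusive ranking is a property one can only plant -- and therefore
  only test -- at the feature level. Cross-validation
  structure is the same 10-inner/5-outer patient-grouped design used
  throughout.

## Known limitations

Full-generality autoreject (Bayesian-optimized consensus) is intentionally
replaced by the CV-threshold variant above. The EDF writer emits EDF+C with
1-s records only. The pipeline treats epoch condition tags as metadata, not
features. Connectivity and other spatially aware features are out of scope,
as is any claim about real-cohort AUC values: the clinical data behind the
motivating study are private, and this package validates machinery, not
clinical effect sizes.
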
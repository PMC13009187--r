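---
title: "Detecting autonomic dysreflexia from wearable biosignals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting autonomic dysreflexia from wearable biosignals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Autonomic dysreflexia (AD) is a hypertensive emergency in people with spinal
cord injury at or above T6: a noxious stimulus below the lesion (classically
bladder distension) triggers unopposed sympathetic discharge and a rapid rise
in systolic blood pressure (SBP). The clinical criterion is a sustained SBP
rise of at least 20 mmHg above the individual's baseline. During a urodynamic
study (UDS) — the bladder-filling examination used to provoke and observe AD
under monitoring — cuff BP is only available every 2–3 minutes, while wearable
sensors stream continuously. `adwear` implements a complete pipeline for
learning to detect AD episodes from those continuous channels, using the
sparse cuff readings only to construct reference labels.

The package handles nine channels from three devices: a multimodal wristband
(PPG at 128 Hz, bioimpedance EDA at 32 Hz, skin temperature at 1/60 Hz, HR
and respiratory rate at 1 Hz), a chest ECG patch (ECG at 128 Hz, HR, RR) and
a temperature patch (core/skin temperature at 1/60 Hz).

## Reference labels from sparse cuff BP

`ad_labels()` implements the labeling rule:

* **Baseline** — the arithmetic mean of the first three SBP readings of the
  session (`compute_baseline()`). Subjects with fewer than three readings
  cannot be labeled and raise an error.
* **Continuous SBP** — a shape-preserving monotone piecewise-cubic Hermite
  interpolant (PCHIP) through the cuff readings, evaluated at 1 Hz and
  clipped to the observed reference span. We compute the knot derivatives
  with the Fritsch–Carlson/Butland rule (weighted harmonic mean of adjacent
  secant slopes, zero at sign changes, clamped one-sided rule at the ends)
  and evaluate with `stats::splinefunH()`. We did not use
  `splinefun(method = "monoH.FC")` because its derivative filter admits a
  small overshoot at interior extrema, violating the no-new-extrema property
  the labels rely on; our derivative rule matches the widely used reference
  implementation of PCHIP and is tested against values computed with it.
* **Threshold** — label 1 wherever interpolated SBP ≥ baseline + 20 mmHg
  (boundary inclusive). "Sustained" is not quantified in the clinical
  definition; the interpolation itself smooths transients, so the default is
  the instantaneous rule, with an optional minimum-duration filter
  (`min_duration_s`, default 0) for sensitivity analyses.
* **Window labels** — a window `[start, end)` is AD when more than half of
  its 1 Hz grid points are positive (`assign_window_labels()`). Midpoint and
  any-overlap rules were the alternatives; majority occupancy was chosen so
  that a 60 s window mostly outside an episode does not count as AD. The
  fraction is configurable.
* **BP-proximity gate** — `gate_by_bp_proximity()` marks windows whose
  midpoint lies within 120 s of some cuff reading. The interpolated label is
  least trustworthy far from any actual measurement, so feature selection
  uses only gated windows. Whether the gate should also restrict final
  training is ambiguous in the source protocol; the default applies it to
  selection only, and `evaluate_loso()` takes the gate as data so either
  choice is a one-line change.

The label grid runs at 1 Hz, matching the HR/RR channels and making
occupancy fractions exact.

## Per-modality conditioning

All filters are zero-phase (forward–backward), so beat fiducial times are not
shifted.

* **PPG** (`ppg_preprocess()`): sign inversion (reflective sensor), 4th-order
  Butterworth band-pass 0.25–10 Hz, baseline removal by asymmetric least
  squares (Whittaker smoother, smoothness λ = 1e7, asymmetry p = 0.01, 10
  iterations — the conventional hyperparameters of that method family), beat
  segmentation by adaptive thresholding of the first derivative with a
  refractory period, per-beat systolic amplitude normalization, and SQI
  rejection of beats whose skewness, kurtosis or SNR leave the subject's
  median ± 3 MAD band (`sqi_thresholds()`; with fewer than 10 beats the
  bounds are universal).
* **ECG** (`ecg_preprocess()`): wavelet shrinkage with the biorthogonal-4.4
  basis (5 levels, soft universal threshold, noise scale from the finest
  detail MAD), baseline correction by sequential median filtering — the
  600 ms filter applied to the 200 ms-filtered signal estimates the baseline,
  which is subtracted (the cascade-estimates-baseline reading of that
  convention) — then R-peak detection with an adaptive steep-slope threshold
  and refractory period (Christov's criterion class), and outlier-beat
  removal: template correlation < 0.8 against the running mean template, or
  R amplitude outside median ± 3 MAD (with a 5 % relative MAD floor so that
  near-identical clean beats are not rejected on numerical noise).
  No R wavelet package is available in this toolchain, so the package carries
  a small periodized DWT/IDWT filter bank (bior4.4 and db3, published filter
  coefficients); perfect reconstruction is covered by tests.
* **EDA/BioZ** (`eda_split()`): tonic level = centered 4 s running median,
  phasic = residual, so the decomposition reconstructs the input exactly.
* **HR and RR** (`normalize_to_resting()`): divided by the median of the
  first 180 s (the pre-provocation phase of a UDS; config-exposed), interior
  gaps linearly interpolated, leading/trailing gaps left missing.
* **Temperature**: no conditioning (1/60 Hz).

## Windowed features

`build_feature_table()` tiles each session with half-open windows (`[start,
start + duration)`, complete windows only) and emits one row per (subject,
window). Feature columns are named `<modality>.<device>.<name>` so each
carries its scope tags; `feature_manifest()` recovers the tags and
`assemble_tables()` builds the nine scope tables (six modalities pooled
across devices, three devices).

Families: HRV time/frequency/Poincaré descriptors from ECG R-peaks and from
the 1 Hz HR channel (mean/min HR, SDNN, RMSSD, pNN50, 80th-percentile and
max NN, LF/HF and total power via a Welch periodogram of the NN series
cubic-interpolated at 4 Hz — frequency features only for windows of ≥ 30 s —
SD1/SD2, and a cumulative mean HR from session start); ECG beat morphology
(QRS width at 2 % of R amplitude, Q–S duration, P/Q/R/S amplitude
differences and ratios, first 8 Daubechies-3 approximation coefficients of
the 64-sample resampled template, 6 Hermite-function projection coefficients
with the width fitted over a small grid, and a rotation-invariant uniform
local-binary-pattern histogram of the QRS segment); PPG pulse-wave indices
(crest time, reflection and augmentation index, LASI, NPV, systolic and
diastolic widths at 25/50/75 % height and their ratios) plus window
statistics (mean, variance, MAD, RMS, skewness, kurtosis, amplitude-histogram
entropy, perfusion AC/DC) and spectral descriptors (fundamental in
0.5–3 Hz, harmonic magnitudes, spectral skewness and energy, wavelet
entropy); EDA tonic statistics and derivatives, SCR count/amplitude/rise
time/area above a 0.01 µS prominence, 0.1 Hz-band powers up to 0.5 Hz and
magnitude-spectrum shape; temperature (and RR) slow-trend features — mean
absolute value and 1st–3rd finite differences over 1/2/3-minute lookbacks,
forward-filled per subject when a sparse channel has no fresh sample.

Per-beat features are aggregated into windows by the median (robust to
residual artifact beats; the mean was the alternative). Missing features are
encoded as missing, never zero — downstream, a learner whose scope features
are entirely missing abstains.

## Feature selection: standardized TreeSHAP vs shadow features

`tree_shap_importances()` z-normalizes the raw features, restricts samples to
the BP-proximity gate, fits an XGBoost ensemble with column subsampling
(mitigating multicollinearity) and computes exact per-sample TreeSHAP values;
local additivity (contributions + bias = model margin) is exposed in
`glance()`. Importance is the mean absolute SHAP value z-scored across
features; per-feature SHAP distributions are standardized as
`z = (φ − mean φ) / sd φ` with the (N−1)-denominator sd
(`standardize_shap()`), features with zero sd flagged degenerate.

`boruta_select()` appends a freshly row-permuted shadow copy of every feature
each iteration, refits, and scores a hit for every real feature beating the
best shadow. Hits are tested per feature with a two-sided binomial test
(p = 0.5) at α = 0.05, Bonferroni-corrected; decisions are sticky, iteration
stops early once every feature is decided, and features still tentative at
`max_iter` (default 500) are rejected.

One design point deserves emphasis. On a *fixed* dataset the feature most
spuriously correlated with the labels keeps that correlation in every
iteration, while each shadow's correlation is redrawn by its permutation; a
deterministic importance estimator therefore lets that one feature beat the
shadow maximum in a large fraction of iterations and be falsely confirmed
even under label permutation. The shadow-loop booster consequently uses
aggressive row subsampling (20 % per iteration) and per-node column sampling
(20 %), making its per-iteration importances behave like bagged-forest
importances: noisy, and with credit shared across correlated columns. Under
label permutation this keeps every feature's hit rate below the binomial
acceptance boundary, while genuinely informative features — whose association
survives any subsample — still hit in essentially every iteration. The
ranking booster outside the loop uses 80 rounds at depth 4 (learning rate
0.1, column subsample 0.7); all booster settings are config-exposed.

Selection runs globally and per scope; `importance_quadrants()` combines the
global and scope-local z-scores for the quadrant view (single-feature scopes
get a local z of 0 and a flag).

## The ensemble

`train_ensemble()` fits nine random-forest weak learners (100 trees each),
one per modality and one per device, on robust-scaled
(median/IQR, statistics from training rows only; zero-IQR features dropped)
and exactly class-balanced data (1:1 random undersampling of the majority
class, seeded). Rows whose scope features are all missing are dropped for
that learner — this is how sensor absence is modeled — and learners with
fewer than 2 minority rows are marked unavailable and excluded from voting.

Aggregation:

* **k-threshold voting** (`k_vote()`): AD iff at least k learners emit a
  probability ≥ 0.5 (the per-learner operating point; the source
  architecture does not state one, and 0.5 matches the balanced training
  classes). Decisions are non-increasing in k, and k = 0 is the always-
  positive boundary row of the timeline plots.
* **Stacked meta-learner** (`train_stacked_meta()`): meta-features are the
  nine learner probabilities, with abstentions imputed at 0.5 (an
  uninformative vote). To avoid leakage, meta-training features are produced
  by inner leave-one-subject-out within the training fold, so no training
  subject's meta-features come from learners that saw it; with fewer than
  three training subjects the code falls back to in-sample meta-features
  with a loud warning (`stacking = "in_sample"` also exposes this mode).
  The candidate bank covers seven families — nearest centroid, logistic
  regression, random forest, gradient boosting, k-NN, naive Bayes, LDA —
  selected by grouped 3-fold cross-validated macro F1 (folds split by
  subject), and is extensible; a bank of 40+ classifiers adds nothing
  methodologically and was deliberately not mandated.

`subset_robustness()` re-aggregates a finished evaluation over learner
subsets (default sizes 4–9; all 511 non-empty subsets when opened to size 1)
by refitting the meta-learner per fold on the stored inner meta-features
restricted to the subset's columns — weak learners are scope-independent, so
the full subset reproduces the full-ensemble result exactly.

## Evaluation

`evaluate_loso()` holds each subject out once per repeat (default 10 repeats
with derived seeds), trains everything on the remaining subjects, and
evaluates on the held-out windows at their original class imbalance. Metrics
(`macro_f1()`, per-class precision/recall/F1, rank-based midrank ROC-AUC) are
pooled over windows within each repeat and summarized as mean ± sd across
repeats; a class with zero true and zero predicted members contributes F1 = 0.
`dummy_baseline()` is the closed form for a constant majority-class
predictor, macro F1 = p/(1+p) with p the majority prevalence.

Feature selection inside the evaluation is `"pooled"` by default (one
shadow-feature run per scope on all gated samples, reused across folds).
Per-fold refitting (`selection = "per_fold"`) is the leakage-safe option and
is implemented and tested, but a full shadow loop per scope per fold per
repeat multiplies the cost by the fold × repeat count (hundreds of runs) for
a selection that is nearly identical on this data; the pooled default is the
pragmatic desk-scale choice and the flag restores the strict protocol.

`window_sweep()` re-runs feature extraction and per-learner LOSO for the six
studied (duration, step) configurations — (5,5), (10,5), (10,10), (30,10),
(60,5), (60,10) seconds — and compares consecutive configurations per learner
with a paired two-sided t-test over repeat F1 values (no multiple-testing
correction, matching the raw-p convention of the analysis it mirrors; a
zero-variance difference reports NA rather than significance).
`prediction_timeline()` exports the matrix view (learner probabilities,
k = 0..9 decisions, meta probability, truth; columns ordered by subject and
time) consumed by `plot_prediction_timeline()`.

## The synthetic cohort

The clinical recordings behind this method are not publicly available, so
`generate_cohort()` builds UDS-like sessions that exercise every pipeline
stage:

* ECG: beat templates (Gaussian P/Q/R/S/T) placed at beat times whose RR
  intervals follow an AR(1) process (φ = 0.9, σ = 25 ms, clipped to
  0.4–1.5 s) around the instantaneous 60/HR mean — this gives realistic SDNN
  and RMSSD magnitudes.
* PPG: two-lobed pulse templates at the same beat times (0.22 s transit
  delay), amplitude jitter, slow drift, stored inverted as a reflective
  sensor would record.
* EDA: smooth tonic level plus Gaussian-bump SCRs from an inhomogeneous
  Poisson process (3/min at rest).
* Temperature: slow drift at 1/60 Hz; HR and RR channels at 1 Hz.
* Cuff BP: the continuous SBP sampled every 2–3 min with 2 mmHg measurement
  noise (cuff grade; small enough to keep labels stable at the 20 mmHg
  threshold).

During an AD episode the SBP rides a smooth logistic ramp (default 60 s
rise, 60 s plateau, ≈ 2-minute episodes), HR shifts by +15 bpm (signed and
configurable, since AD can present with brady- or tachycardia; the positive
default keeps HR features informative), the SCR rate quadruples and the
tonic level rises by 1.5 µS, and temperature drifts upward beginning 60 s
*before* onset — emulating the early thermal response that motivates
temperature as an early-warning channel. Episode onsets fall at 45–60 % of
the session, after the three baseline cuff readings, as in a protocol where
provocation starts after baseline.

What the generator does **not** emulate: real waveform morphology and
artifacts (motion, contact loss beyond the explicit failure injector),
between-subject physiological heterogeneity beyond randomized baselines, and
any coupling between channels other than the scripted episode response.
Passing the synthetic acceptance properties therefore demonstrates that the
pipeline recovers known injected structure end-to-end — not that it attains
any particular performance on clinical data.

`inject_channel_failure()` degrades a modality by contiguous dropout blocks
or by Gaussian noise scaled to the channel IQR, for the sensor-failure
robustness experiments.

## Problem sizes used in the automated runs

The shipped tests and the acceptance script use a scaled-down study
condition chosen once: 17 subjects of whom 7 have AD episodes (the cohort
ratio of the motivating study), 7-minute sessions with cuff readings every
~55 s — preserving the ~8–9 references per session of a full-length UDS at
reduced duration — one ~2-minute episode per AD subject, the (60 s, 10 s)
window configuration for the headline run, and 10 evaluation repeats. The
selection simulations use 5 informative + 50 noise features at n = 2000 over
10 seeds. These sizes are the package's own desk-scale choices; every one of
them is a parameter of the public API.

## Known limitations

* Only affine clock alignment is modeled; residual nonlinear drift between
  devices is not corrected (the motivating protocol had two anchor events,
  which determine exactly an affine map).
* The AD criterion is SBP-based only; DBP/MAP criteria and orthostatic
  hypotension detection are out of scope.
* Motion-artifact handling is limited to the SQI beat filters.
* The stacked aggregator's candidate bank is deliberately compact (seven
  families); the interface accepts user-supplied candidates.
* Probability calibration and cost-sensitive operating points are not
  implemented; the 0.5 vote threshold reflects balanced training classes.
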
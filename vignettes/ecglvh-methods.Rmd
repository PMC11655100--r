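---
title: "Methods: ECG feature extraction and LVH classification in ecglvh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG feature extraction and LVH classification in ecglvh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecglvh)
```

## The problem

Left ventricular hypertrophy (LVH) — thickening of the left ventricular
wall — is a strong risk factor for cardiovascular morbidity, and the
resting 12-lead ECG is the cheapest screening instrument for it. The
classical voltage criteria (Sokolow–Lyon, Cornell-type products, total
12-lead voltage and their relatives) are very specific but notoriously
insensitive, so a large fraction of hypertrophic patients go undetected.
`ecglvh` implements a feature-based machine-learning alternative: it
delineates the 12-lead ECG, extracts three families of features, evaluates
22 codified voltage criteria for comparison, and trains class-balanced
classifier ensembles that trade a little of the criteria's specificity for
a large gain in sensitivity.

Everything in the package can be exercised on synthetic records from the
built-in generator, so the full pipeline is testable without access to
clinical databases. The same functions accept real WFDB records (the
format used by the large public 12-lead ECG repositories).

## The synthetic generator

`generate_record()` builds each lead as a train of beats, each beat a sum
of five Gaussian-shaped waves (P, Q, R, S, T) with per-lead amplitude,
center offset relative to the R peak, and width. The T wave may be made
asymmetric with two half-Gaussians (`t_asym`, default 1.2), so ascending
and descending T slopes differ as they do on real ECGs. The default
amplitudes follow textbook adult morphology (tall mid-precordial R, deep
right-precordial S, negative aVR); the LVH-like class adds the classic
voltage/strain pattern: +0.8 mV R in V5/V6/I/aVL, 0.8 mV deeper S in
V1/V2, T inversion in V5/V6, and Q/R/S widths scaled by 1.33, which
stretches the QRS by roughly 20 ms.

Ground-truth fiducials are analytic: wave peaks at the Gaussian centers,
onsets/offsets where a wave reaches 1% of its own peak amplitude
(`onset_frac`), QRS onset/offset as the extreme onset/offset over the
present Q/R/S waves. This gives every downstream stage an exact oracle.

Record-to-record variability is controlled by five knobs, chosen once to
mimic a screening population and not revisited:

* heart rate 60 ± 2 bpm across records, ±10 ms RR jitter within a record;
* a global per-record amplitude scale factor with SD 0.15 (body-habitus
  variation — this is what makes individual voltage criteria miss small-
  voltage LVH, as they do clinically);
* independent per-lead, per-wave amplitude jitter with CV 0.10;
* additive white noise with SD 20 µV;
* sinusoidal baseline wander of 50 µV at 0.15–0.4 Hz.

Determinism is bit-exact: one seed drives a single RNG stream per record,
and cohorts derive per-record seeds as `seed + index`.

What the generator does **not** emulate: ectopy and arrhythmia, QRS
fragmentation and notching, electrode artifacts, muscle noise, pathologies
other than the single LVH-like pattern, and the physiological correlation
structure a vectorcardiographic lead model would impose. Passing tests on
synthetic cohorts therefore demonstrate correctness of the machinery and
the stated statistical properties, not clinical performance.

Throughout the package sample indices are 1-based (the R convention), and
all amplitudes are stored in mV; conversion to millimeters of standard ECG
paper (10 mm/mV) happens only inside the criteria module.

## Delineation and beat-quality control

R peaks are detected on lead II with a Pan–Tompkins-style transform
(5–15 Hz band-pass, derivative, squaring, 150 ms moving-window
integration) with adaptive signal/noise thresholds and a 200 ms refractory
period; candidates are refined to the raw signal's largest absolute
deviation, which makes the detector polarity-insensitive. The lead II
anchors are reused on all leads, where the per-lead R is re-localized in a
narrow ±10 ms window (R is near-simultaneous across leads; a wider window
would lock onto a deep right-precordial S).

Q and S are the extrema of polarity opposite to R within ±80 ms. QRS
onset and the J point are found by walking outward from Q/S until the
signal re-enters a tolerance band around the baseline; the band is 1% of
the wave's own peak amplitude with an absolute floor of 2.5 estimated
noise SDs. The noise SD is estimated per lead from the median absolute
second difference (near zero for a smooth ECG, `sqrt(6)·sd` for white
noise), so clean signals keep the exact 1% rule — on zero-noise synthetic
records ≥ 99% of landmarks are recovered within 2 samples. The per-beat
baseline is the median of the 40 ms PR-segment window ending 20 ms before
QRS onset. P and T peaks are the extrema in [R−300, R−100] ms and
[J+80, J+420] ms respectively; signs are preserved (an inverted T has a
negative amplitude), and waves below the presence threshold (25 µV or the
noise floor) are flagged absent rather than fabricated.

Quality control follows the template-correlation principle: beats are
aligned on R over a window from the median QRS onset −150 ms to the median
T offset +50 ms, each beat is linearly detrended using its two isoelectric
anchor regions (PR segment and post-T tail), and beats correlating < 0.90
with the pointwise median beat are dropped. If fewer than 5 beats survive
on any lead, the record is excluded with a reason code. The thresholds
(`min_beats = 5`, `min_corr = 0.90`) are package defaults, configurable;
they encode the principle that a usable record needs a minimum number of
low-deviation beats.

## Feature families

**Morphological (19 per lead, 228 per record).** Signed amplitudes at P,
Q, R, S, J, T relative to the beat baseline; the R/P and R/T ratios of the
median amplitudes (denominators under 0.01 mV give a missing value rather
than a blow-up); the PR, PS, PT, QT, QRS, RS, ToT and TTe intervals in ms;
the two-point secant slopes of the ascending and descending T limb in
mV/s; and the percentage of QRS samples strictly below baseline. Per-beat
values are aggregated by the median, so a single aberrant beat cannot move
a feature. Interval endpoints are the conventional readings of the names:
PR = P onset → QRS onset, PS = P onset → S, PT = P onset → T offset,
QT = QRS onset → T offset, QRS = QRS onset → J, RS = R → S,
ToT = T onset → T peak, TTe = T peak → T offset. ToT could also be read as
starting at the T offset; the onset→peak reading was chosen as the
conventional one and is configurable in spirit — the endpoints are plain
landmark differences in one function.

**Hermite decomposition (5 per lead, 60 per record).** The averaged QRS of
each lead (QRS onset −20 ms to J +20 ms of the template, baseline
subtracted) is projected onto the first four orthonormal Hermite
functions, time axis centered on R. The basis time scale σ is not
prescribed by the underlying theory, so it is chosen per lead by a grid
search over `qrs_duration / k`, k = 4…10, keeping the σ with the smallest
fit RMSE; σ is stored with the fit so coefficients remain interpretable.
The RMSE between template and reconstruction is reported in µV and doubles
as a morphology-complexity feature: 4 coefficients fit a smooth QRS almost
perfectly, so a high residual flags fragmented or noisy complexes. Rows of
the basis are normalized to unit L2 norm on the grid in the
grid-spacing-weighted sense, which keeps the continuous-time scaling law
`sqrt(2)·Φ_i^{2σ}(2t) = Φ_i^{σ}(t)` and makes the discrete Gram matrix the
identity to numerical precision.

**V-index (1 per record).** The V-index estimates the standard deviation
of ventricular repolarization times from the cross-lead spread of the
second-order dominant-T-wave model. T-wave segments of the lead templates
(T onset −10 ms to T offset +10 ms, on a common grid) are stacked into a
matrix Ψ; the dominant T-wave T_d is its first singular direction (sign
fixed against the mean row), and each lead is regressed as
Ψ_ℓ ≈ w₁(ℓ)·T_d + w₂(ℓ)·Ṫ_d. The index is sd[w₂]/sd[w₁], in ms. Only the
eight linearly independent leads (I, II, V1–V6) enter: the augmented limb
leads are deterministic combinations of I and II and would artificially
shrink the cross-lead standard deviations. One index is computed per
record from the templates; beat-to-beat V-index dynamics are out of scope.
On ensembles simulated from the two-term model itself with a 30 ms spread
ratio and up to 5% noise, the estimator recovers the ratio with a median
relative error under 10% (this is verified in the acceptance suite).

A record's assembled feature row has 19×12 + 5×12 + 1 = 289 named values
(`R_amp_V5`, `herm_c1_I`, `T_slope_des_aVR`, …, `v_index`); missing
landmarks propagate as missing features.

## The 22 voltage criteria

`evaluate_criteria()` codifies 22 classical criteria (Lewis, Gubner,
Sokolow–Lyon, Goldberger, Schack, Romhilt, Wilson, Mazzoleni, Murphy,
Grant, Holt, McPhie, Wolff, Siegel, Molloy). Wave symbols in the formulas
denote amplitude *magnitudes* in mm at 10 mm/mV — the criteria are
positive voltage sums, and signed arithmetic would invert their meaning;
under this convention the Lewis formula reproduces the classical
(R_I + S_III) − (R_III + S_I) index. "Any lead" clauses take the maximum
over the named leads, total 12-lead voltage is Σ(|R|+|S|) over all leads,
and the two Molloy products multiply by the QRS duration in ms.
Inequalities are strict, exactly as codified; boundary equality is
negative. A missing operand makes the criterion missing, and missing
results count as negative inside `combine_any()`, the "at least one of"
combination rule whose default set is the five criteria with the best
standalone discrimination (Siegel, McPhie, Sokolow–Lyon1, Grant2,
Romhilt1). Two quirks are intentional and kept as codified rather than
"corrected": Gubner1 is a difference R(I) − S(III) although the historical
index is usually quoted as a sum, and both Molloy products share the 2436
threshold.

## The learning pipeline

* **Feature selection** (`sffs_select`) is sequential floating forward
  selection scored by the mean AUC over five Monte-Carlo stratified 70/30
  splits (the same splits for every candidate subset, so comparisons are
  paired). Forward steps add the best feature; floating backward steps
  remove a feature whenever removal strictly improves the best AUC
  recorded at the smaller size, which guarantees termination. The search
  caps at 30 features; the selected subset is the best-mean-AUC subset
  visited, and `sffs_top_k()` returns the first k features in selection
  order for reduced models.
* **Training** (`train_with_cv`) uses k = 10 stratified folds. The
  training part of each fold is balanced by down-sampling the majority
  class, independently per fold; missing values are imputed with
  training-part medians and (for logistic regression and SVM) columns are
  standardized with training-part statistics only. Out-of-fold scores are
  pooled for the cross-validated AUC and for the operating threshold — the
  pooled-out-of-fold choice is deliberately the less optimistic of the two
  possible readings (the alternative is scoring the refit model on its own
  training data). The final learner is refit on the full balanced data.
* **Threshold** (`choose_threshold`) minimizes FPR² + (1−TPR)² over all
  realizable score cuts — the operating point closest to the perfect
  corner (0, 1) of the ROC plane. Ties break toward the more specific
  (larger) threshold. The three learner kinds are logistic regression,
  random forest (150 trees) and an RBF-kernel SVM whose decision values
  are mapped to (0, 1) by the usual monotone logistic (Platt)
  calibration, so the same threshold geometry applies to all three; AUC
  and the corner objective are invariant under monotone score mappings.
* **Ensembling** (`build_ensemble`, `predict_majority`) trains 100 members
  (10 in the desk-scale acceptance runs) with independent derived seeds,
  so each member sees a different down-sampling draw; each full
  cross-validation is re-run per member rather than only the down-sampling
  draw, the more conservative of the two readings. Members vote with
  their own thresholds; the majority label wins and an exact tie takes the
  first member's vote, which is why member order is persisted with the
  model.

All seeds (fold assignment, per-fold balancing, member seeds) are derived
deterministically from the master seed and stored in the model objects, so
a saved ensemble reproduces its predictions exactly.

## Numerical choices and degenerate inputs

* Flat signals raise a no-beats error; beats whose search windows cross
  the record edge are skipped, not padded.
* An all-zero QRS window yields zero Hermite coefficients and zero RMSE.
* A rank-0 T-wave ensemble and a numerically collinear (T_d, Ṫ_d) pair are
  errors; sd[w₁] = 0 makes the V-index undefined (missing, with a
  warning).
* Constant feature columns are excluded from selection up front; zero-SD
  columns get unit scale during standardization.
* Amplitude-ratio denominators under 0.01 mV and criteria with missing
  operands propagate missingness instead of producing extreme values.

## Problem sizes used by the tests

The acceptance suite simulates a 200 + 200 training cohort and a 100 + 100
validation cohort at the default study conditions, trains 10-member RF and
SVM ensembles on all 289 features, and checks AUC > 0.9, sensitivity > 0.8
and balanced accuracy > 0.85 on the held-out set — properties of the
generator's configured class separation, chosen to keep a full run on one
CPU within minutes. Statistical property checks use 200 replicates
(V-index recovery), 100 random instances (threshold oracle), 50 simulated
datasets (single-feature selection oracle) and 20 seeds (planted-feature
selection).

## Known limitations

The delineator is intentionally simple (single-lead anchors, threshold
walks); it is accurate on clean morphologies and degrades gracefully under
noise, but it is not a clinical-grade delineator and the package accepts
external fiducials through the CSV interchange format for exactly that
reason. The QRS-duration estimate shortens under heavy noise because the
tolerance band widens with the noise floor. Synthetic separability is
configured, not discovered: classifier metrics on synthetic cohorts say
nothing about performance on clinical data, for which the WFDB reader and
the label-file dialects are provided.
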
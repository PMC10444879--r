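---
title: "tapscore: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tapscore: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how `tapscore` measures finger-tapping severity, why
each tunable is set the way it is, and which design points were genuinely
open calls. It states no empirical result beyond what the package's tests
and `scripts/acceptance.R` themselves compute.

## The measurement model

The MDS-UPDRS finger-tapping item (3.4) scores speed, amplitude,
hesitations and amplitude decrement on a 0–4 scale. The pipeline assumes a
single target hand recorded at an approximately constant frame rate, with a
21-landmark pose estimate per frame carrying a handedness label, a
classification score and a hand-presence score. Tap aperture is the angle
at the wrist between the thumb-tip and index-tip vectors, converted to
degrees; being an angle it is invariant to where the camera sits, which is
the reason for preferring it over fingertip distance. We use the standard
radians-to-degrees conversion (×180/π), so angles live in [0, 180].

When several hands match the requested category (another person in frame),
the subject is assumed closest to the camera, hence the detection with the
largest wrist-to-thumb-tip distance wins; exact ties keep the
earliest-listed detection, purely for determinism.

Cleaning runs in a fixed order — angle construction, interpolation of
isolated missing values, longest visible segment, peak detection, trimming
— matching the narrative order in which the steps are meaningful.
Interpolation before segmentation can in principle bridge two visible runs
into one; we accept that, since a bridged gap requires a local majority of
visible neighbours.

## Peak detection

Tap peaks are strict local maxima filtered by three task-specific rules:

1. *A peak is followed by a bottom*: between consecutive accepted peaks some
   sample must fall at least `trough_iqr_fraction` (default 0.2) of the
   signal's interquartile range below the earlier peak. The fraction is a
   config key because "a bottom" is qualitative; 0.2·IQR is small enough to
   pass genuine inter-tap valleys and large enough to reject dimples on a
   rising flank.
2. *Minimum inter-peak gap*: `min_peak_gap_s` (default 0.1 s). Ten taps per
   second exceeds any plausible human tapping rate, so no true tap is lost.
3. *Amplitude floor*: a peak must exceed the 25th percentile of the
   analyzed signal (`amplitude_floor_quantile`), the most literal reading of
   "bigger than the smallest 25-percentile values".

Candidates are scanned left to right; when a candidate violates rule 1 or 2
against the last accepted peak, the larger of the two survives. The test
suite holds this implementation equal, decision for decision, to an
independent exhaustive oracle on 100 random smooth signals.

Because participants position the hand before tapping and withdraw it
after, the signal is trimmed to the span from the second to the
second-to-last peak; exactly two peaks are always removed.

## The 65-feature registry

The registry is a versioned constant (`featureRegistry()`, version 1):

* 35 features: {median, IQR, mean, min, max, SD, entropy} × {speed,
  acceleration, period, frequency, amplitude}. Frequency aggregates come
  from per-tap frequencies (1/period), not from tap count over duration.
* 12 rhythm/hesitation features: spectral aperiodicity; interruption count
  (speed < 50°/s for ≥ 10 ms); freezing count and longest freezing duration
  (< 50°/s for > 20 ms, strict); period-linearity R² and slope; period
  fitting complexity (smallest polynomial degree 1–10 reaching R² ≥ 0.9,
  11 if none); amplitude end−mean, end−begin, and slope; period variance
  normalized by the mean period; retained tap count.
* 18 wrist features: {median, IQR, min, max, SD, entropy} × {ΔWX, ΔWY, ΔW},
  computed over the same trimmed segment as the tapping features so the two
  groups describe the same time window.

The group sizes (47 tapping + 18 wrist) are pinned by acceptance tests. The
published feature counts over-determine the enumerated lists, so two
choices close the inventory: the wrist group takes six aggregates (the
seven minus the mean, which is nearly redundant with the median for these
skewed displacement distributions), and the tapping group includes the
normalized period variance and the tap count. "End" and "beginning"
amplitudes are single taps by default (`end_taps_k = 1`); a k-tap mean is a
config key.

Thresholds worth restating with units: speed floor 50 °/s; interruption
duration ≥ 0.010 s; freezing duration > 0.020 s (so at 30 fps a single slow
frame, 33 ms, is already both); presence gate 0.90 (frames below it are
missing); handedness score gate 0.9. The two 0.9 thresholds are distinct
config keys because they gate different estimator outputs.

## Numerical choices

* **Distribution entropy** is Shannon entropy (natural log) over a 10-bin
  equal-width histogram spanning the observed range (`entropy_bins`). A
  sequence whose range is below 1e−9 (relative) is treated as constant with
  entropy 0: without that floor, femto-degree noise would spread an
  essentially constant sequence across bins and jump the entropy
  discontinuously — this is what makes the entropy features stable under
  rigid-motion perturbations of the landmarks.
* **Aperiodicity** removes the mean, takes the one-sided power spectrum
  excluding DC, normalizes it to sum 1, and returns its Shannon entropy. A
  constant signal returns 0 by convention.
* **Interpolation** fits one polynomial of degree 3 (`interp_degree`) to
  all visible samples and evaluates it at missing positions, clamped to
  [0, 180]. Degree 3 follows the signal's slow envelope without the
  oscillation a high-degree fit shows on long signals. "Majority" means
  strictly more than half of the up-to-10 available neighbours.
* **Zero-variance conventions**: period linearity has R² = 1 and slope 0
  for constant periods (a flat line is a perfect fit); fitting complexity
  is then 1.
* **Class conversion** rounds half-points up (1.5 → 2), documented rather
  than IEEE round-half-even, so thresholds are predictable.
* **Greedy redundancy filter** scans pairs in registry order and drops the
  later column of any pair with |r| > 0.85, so the kept member of each
  correlated cluster is deterministic. Constant columns (undefined r) are
  kept but flagged.
* **Recursive feature elimination** refits a boosted-tree learner, drops
  the single weakest feature by gain (ties: the latest column), and repeats
  to k = 22. Zero-gain features (never split on) drop first.

## Invariances — what holds and what cannot

Rotation, translation and uniform scaling of all landmarks leave the
tapping-angle features unchanged (angles are frame-invariant) and leave the
Cartesian wrist displacement ΔW unchanged (the per-frame normalization by
the wrist-to-thumb-base distance cancels scale). Two caveats are inherent
to the wrist formulas, not to this implementation:

* ΔWX and ΔWY are *axis-referenced* absolute coordinate differences, so
  their aggregates cannot be rotation-invariant — rotating the camera mixes
  the x and y components. The invariance tests therefore check rotation on
  every feature except the twelve wrist x/y-component aggregates.
* Translation cancels exactly only while the normalizing wrist-to-thumb-base
  distance is constant across frames. With per-frame landmark noise the
  denominator varies, leaving a residual translation sensitivity of order
  noise × offset. The invariance tests run with noise-free coordinates;
  users comparing wrist features across recording setups should expect this
  residual on real data.

## The severity model

The default regressor is a gradient-boosted decision-tree ensemble with
leaf-wise (loss-guided) tree growth — the growth strategy of the LightGBM
family — as implemented by xgboost with `grow_policy = "lossguide"`.
Hyper-parameters are fixed, documented defaults (learning rate 0.1, 31
leaves, 150 rounds, single thread): reproducibility is preferred over a
hyper-parameter search, which is out of scope. Features are standardized
(zero mean, unit variance) with statistics fitted on training rows only;
min–max scaling is a config alternative. Minority oversampling is
deliberately not implemented — it degraded performance in the study this
design follows — and the config key `smote` exists only to document that
decision.

Cross-validation is leave-one-patient-out: all of a participant's rows
(both hands) are held out together, one fold per participant. Whether the
redundancy filter and feature selection belong inside each fold is genuinely
ambiguous in the source material; the default re-runs them per fold (the
leakage-safe reading), and `paper_mode = TRUE` reproduces whole-table
screening for comparability. The significance screen is report-only in
either mode: features can carry non-linear signal that a Pearson screen
misses, so all post-filter features remain model candidates.

Attributions use TreeSHAP (xgboost's `predcontrib`), whose per-row values
are additive to the raw, unclipped prediction; global importance is the
mean absolute attribution.

## Rater statistics

Ground truth is the modal expert rating when at least two of three experts
agree, else the mean rounded to the nearest integer; with three integer
ratings the mean is a multiple of 1/3, so the half-point case cannot occur.
Non-expert ratings never enter ground truth.

The ICC variant is not identified in the source material, so it is a config
choice: the default is two-way random effects, absolute agreement, single
rater, with F-based confidence intervals (Satterthwaite degrees of freedom
for the agreement variants); consistency and average-rater variants are
selectable. Krippendorff's alpha defaults to the ordinal metric — the 0–4
scale is ordinal — with interval and nominal metrics available; the
implementation is the standard coincidence-matrix algorithm and tolerates
missing ratings. Both statistics are checked against independent
textbook-formula oracles in the test suite.

## The synthetic generator

The generator emulates: quasi-periodic tapping-angle arches with a
controllable amplitude schedule (base + per-tap slope), tap frequency,
period jitter, planted freezing/interruption pauses, wrist drift (random
walk), i.i.d. landmark noise, and missing frames; severity-dependent cohort
regimes whose median-speed proxy (2 × amplitude × frequency) and amplitude
strictly decrease with severity while jitter and freeze counts increase;
and a simulated rating panel (three experts, two non-experts) that deviates
from the true severity by ±1 with configurable probability.

Two generator choices deserve explanation:

* **Waveform.** Arches are power-of-triangle, `baseline + A·(1 − |2u −
  1|)^γ` over tap phase `u`, with γ = 1 by default. A smooth (sinusoidal)
  maximum sampled at 30 fps puts adjacent frames astride the peak where the
  derivative vanishes, producing one spurious sub-50°/s frame — a false
  "freezing" event — at every tap. Real tapping reverses direction sharply
  at both finger contact and maximal aperture; the triangular arch encodes
  that, keeps the within-tap speed constant at 2·A·f (well above the 50 °/s
  floor for all but the severest regimes), and makes planted pause counts
  exactly recoverable.
* **Frame quantization.** Tap periods are rounded to even frame counts so
  every peak lands exactly on a sampled frame: amplitudes are then exact
  and realized periods differ from the requested 1/frequency by at most one
  frame duration, which is the tolerance the recovery tests use.

What it does **not** emulate: pose-estimator failure modes (jitter bursts,
identity switches), tremor superimposed on the tapping motion, variable
frame rates, camera motion, lighting artifacts, or raters whose bias
depends on severity. Passing the recovery and model tests therefore shows
that the pipeline measures what the generator planted — it does not certify
performance on real home video, where the published experience is markedly
noisier.

Default cohort conditions: 100 participants, two hand-videos each, severity
proportions (0.22, 0.37, 0.29, 0.11, 0.01) dominated by mild scores as in
clinical samples, expert deviation probability 0.25. The test suite and the
acceptance script use exactly these conditions; the LOPO computation on 200
videos with in-fold feature selection runs in a few minutes on one core,
which is the problem size the package documents and tests.

## Known limitations

* Tremor can destabilize peak detection; no tremor-specific denoising is
  attempted (a smoothing step would alter the speed statistics it feeds).
* Variable-frame-rate video is approximated by one constant frame duration
  (total duration / frame count) per video.
* The severity-4 class is rare under the default proportions; per-class
  behaviour at the top of the scale is weakly exercised.
* The released-data loader maps external column layouts by configurable
  prefixes; layouts that diverge from the documented default need an
  explicit `column_map`.
* The video adapter is a capability stub: turning raw video into landmarks
  requires an external pose estimator that this package intentionally does
  not bundle.
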
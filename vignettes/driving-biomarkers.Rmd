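---
title: "Methods: naturalistic-driving digital biomarkers for early MCI detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: naturalistic-driving digital biomarkers for early MCI detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mild cognitive impairment (MCI) is the transitional stage between normal
aging and dementia. Driving is one of the most cognitively demanding everyday
activities — it loads decision making, divided attention, working memory and
spatial orientation simultaneously — so subtle cognitive decline can surface
as measurable changes in naturalistic driving behavior long before it is
obvious in the clinic. `mcidrive` implements a complete analysis pipeline
that turns raw in-vehicle sensor streams (1 Hz GPS; 24 Hz accelerometer and
gyroscope) into trip- and turn-level multivariate time series, trains
deep-learning classifiers to label each *trip* as cognitively normal or
impaired, and aggregates trip decisions into an interpretable per-driver
risk score.

Two design commitments run through the package:

* **Participant-stratified evaluation.** Trips from the same driver are
  highly correlated; a split that lets one driver's trips reach both sides
  of a fold inflates performance. All cross-validation here is by
  participant, with stratification of the diagnostic groups across folds,
  and the disjointness of train and test participants is asserted as a hard
  error, not a convention.
* **Episodic impairment.** Cognitive performance in MCI fluctuates from day
  to day, so an affected driver may look normal on most trips. The pipeline
  therefore classifies trips individually and reports the *proportion of a
  driver's trips flagged impaired* — a frequency-based risk score in
  `[0, 1]` — instead of a single majority-vote label, which would mask
  exactly the sporadic pattern that matters for early screening.

## Pipeline overview

1. **Cleaning and synchronization** (`clean_cohort()`). Continuous per-sensor
   recordings are segmented into trips wherever the timestamp gap exceeds
   60 s. A mismatch check compares per-sensor trip counts; trips are matched
   across sensors by timestamp overlap, and only trips with all three
   sensors present survive. Inertial channels are block-averaged onto the
   1 Hz GPS grid: samples with time in `[g, g + 1)` belong to GPS second
   `g`, ragged final blocks use the samples available. Rows with missing
   values are dropped (and the trip flagged); trips shorter than 30 merged
   rows — less than one turn window — are excluded. Every exclusion is
   logged with participant, trip and reason.
2. **Turn extraction** (`extract_turns()`). GPS coordinates are projected to
   a local plane with `x = R·λ·cos(φ₀)`, `y = R·φ` (R = 6371 km, reference
   latitude φ₀ = per-trip mean). Samples where the path direction changes by
   more than 10° (0.174533 rad) between successive steps are turn
   candidates; stationary samples (speed 0) are discarded; runs of adjacent
   candidates merge to their median index; a ±15 s window (31 rows at 1 Hz)
   is cut around each peak, with boundary-truncated windows linearly
   interpolated back to 31 rows.
3. **Feature engineering** (`build_channel_set()`). Ten channels in fixed
   order: speed, three accelerometer axes, three gyroscope axes, and three
   derived angular accelerations (temporal gradients of the gyroscope
   channels). The nontemporal baseline uses 14 static features per trip:
   mean and population SD of the seven raw sensor channels, fed to a random
   forest.
4. **Tensorization** (`build_trip_tensor()` and friends). Variable-length
   trips are linearly resampled over normalized time to a common length
   (default L₁ = 1200) and stacked into an N × C × L array. Turn windows are
   either kept per turn (N × 10 × 31) or concatenated per trip and resampled.
   Early fusion concatenates trip and turn sequences along the channel axis
   (N × 20 × L₁); late fusion keeps them as an aligned pair at lengths L₁
   and L₂.
5. **Models and training** (`model_spec()`, `train_model()`,
   `cross_validate()`). Nine reference families across three architecture
   groups — 1-D convolutional (plain CNN, TinyFCN, two reduced Inception
   variants, a residual network), recurrent (GRU, LSTM, optionally with
   additive attention pooling over time) and temporal convolutional (dilated
   causal stacks, optionally with learned-query attention pooling) — plus
   dual-encoder late-fusion variants whose latents merge by concatenation or
   a learned sigmoid gate `g·z_trip + (1 − g)·z_turn`. All are trained
   identically: class-weighted cross-entropy (`w_c = n/(2·n_c)`), AdamW with
   learning rate 1e-3 and decoupled weight decay 1e-4, cosine-annealed to 0
   with period equal to the epoch count (default 200), batch size 32,
   optional per-channel standard scaling fit on the training fold only.
6. **Risk scoring** (`risk_score()`). Per participant: the proportion of
   trips classified impaired, thresholded at 0.1 (sensitivity-first
   screening) and 0.5 (precision-first), compared against the majority-vote
   baseline; `threshold_curve()` sweeps the whole trade-off.

```{r example}
library(mcidrive)
cfg <- pipeline_config(
  cohort = cohort_config(
    trips_per_participant = c(3, 8), trip_duration_s = c(120, 420),
    turn_count_per_trip = c(2, 6), seed = 1
  ),
  l1 = 240,
  train = train_config(epochs = 12, seed = 1),
  seed = 1
)
res <- run_experiment(cfg, "1a")
res$results
autoplot(res$risk)
```

## The synthetic cohort generator

The cohort the original analysis was designed around is private, so the
generator is a first-class module that emulates the statistical structure
the pipeline assumes, with ground truth retained for recovery tests.

* **Route model.** Each trip is a 2-D waypoint polyline: straight segments
  of at least 35 s joined by corners of 60–120°, traversed at per-segment
  cruise speeds of 8–15 m/s with a smooth slow-down through corners. Heading
  integrates a yaw-rate series carrying a rectangular pulse at each corner
  (the planted turn, unfolding over 6 s) plus Gaussian jitter (SD
  0.02 rad/s); position integrates speed and heading at 24 Hz; GPS
  subsamples every 24th point. Accelerometer channels follow the kinematics
  (longitudinal = dv/dt, lateral = v·yaw rate) plus noise.
* **Impairment signature.** Impaired trips multiply the *within-turn*
  (±15 s) fluctuation SD of speed and yaw rate by `effect_size`, modeling
  the frequent steering and speed micro-adjustments associated with reduced
  motor control and cognitive instability in maneuvers. `effect_size = 1`
  reproduces the null exactly: the groups are then exchangeable, which the
  test suite verifies with two-sample KS tests on per-trip summary features.
* **Sporadic expression.** Each MCI trip expresses the signature with
  probability `impaired_trip_fraction` (a per-trip Bernoulli gate), so the
  cohort can emulate drivers impaired on only a minority of trips.
* **Defaults.** 12 healthy + 7 MCI participants with 3–46 trips each,
  mirroring the retained-trip spread of the cohort the package emulates;
  `effect_size = 2.5`; sensor malfunctions (whole-trip sensor dropouts,
  mid-trip cutoffs, blanked values) off by default and injectable at
  configurable per-sensor rates to exercise the cleaning rules.
* **What it does not emulate.** Road networks, traffic, realistic vehicle
  dynamics beyond kinematic jitter, age/sex effects, GPS multipath error.
  Passing recovery tests on this generator demonstrates that the pipeline
  detects the kind of signal it is designed for at realistic sample sizes —
  not that real MCI driving carries that signal; that evidence can only come
  from real cohorts.

## Numerical and design choices

* **Projection.** The source formulation gives `dy/dx` thresholding on
  projected coordinates; we operationalize "gradient shift" as the change in
  path *direction angle* computed via `atan2` of the increments, which is
  immune to the undefined-slope case at due-north headings. The classical
  slope formulation (with its documented `dx = 0` discard) is available as
  `turn_params(mode = "slope")` for compatibility; the 10° threshold applies
  to the angular change in both modes.
* **Run merging.** "Sequential" candidates merge when at most 2 samples
  apart; even-length runs take the lower median (deterministic tie-break).
  With this merge step, raising the threshold can in contrived cases split
  one merged run into two peaks, so the peak-count monotonicity property is
  asserted on paths whose maneuvers are separated by more than the merge
  gap — the regime real trips occupy.
* **Derivatives.** Angular accelerations use second-order central
  differences with one-sided endpoints (exact for linear signals, length
  preserving), computed on the merged 1 Hz grid that the tensors consume.
* **Interpolation.** Linear, over normalized time, per channel: monotone
  safe, endpoint exact, and the identity when input and target lengths
  agree.
* **Block averaging.** Samples are assigned to GPS second `g` by
  `floor(t) == g`; the merge key is the full timestamp (the abbreviated
  calendar key of the source description is ambiguous across year
  boundaries and omits seconds).
* **Zero-turn trips** in fusion modes are zero-padded with a mask flag
  (policy `exclude` available), keeping N aligned across input modes.
* **L₂ = 310** (ten native-resolution turn windows) is the default
  late-fusion turn-branch length; the trip branch keeps L₁ = 1200.
* **Ties and thresholds.** Trip classification thresholds probabilities at
  0.5; the majority vote labels a driver impaired at risk ≥ 0.5, so an
  exact half split flags — screening favors sensitivity.
* **AUC** is the Mann–Whitney rank statistic on pooled test-trip
  probabilities per fold, averaged unweighted across folds; folds whose test
  set holds one class contribute no AUC (the statistic is undefined there).
* **Weight decay** applies to all parameters uniformly (including
  normalization parameters), matching the single decay constant of the
  training recipe.
* **Reference architectures.** The family names fix the design space but
  not every layer width; the variants here are the smallest standard
  instantiations of each name (TinyFCN = three conv blocks of 32/64/32
  filters with kernels 8/5/3, batch norm and ReLU, global average pooling,
  linear head; TCN = four dilated causal levels at dilations 1/2/4/8; GRU /
  LSTM hidden size 64; Inception variants with 2–3 reduced blocks;
  "multihead" attention = four additive score heads; "self" attention =
  learned-query dot-product pooling). Parameter counts are deterministic
  given the spec and seed.
* **No deep-learning framework dependency.** The layer kernel (convolution
  via batched im2col GEMM, batch normalization, recurrent cells with full
  backpropagation through time, attention pooling, AdamW, cosine schedule)
  is implemented in base R matrix algebra; analytic gradients for every
  family are verified against central finite differences in the test suite
  (worst-case absolute deviation below 1e-6 on probe entries).

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on deliberately small cohorts (a few
participants, 1–3 minute trips). The two simulation-heavy checks use the
full 19-participant cohort structure (12 healthy + 7 MCI) with scaled trip
counts and lengths, chosen once as a realistic desk-scale configuration:

* **Signal recovery / null calibration.** 5–14 trips per participant of
  2–7 minutes (about 180 trips per cohort), trips resampled to L₁ = 240
  (matching that trip-length distribution the same way the full-scale
  default L₁ = 1200 matches longer naturalistic trips), trip-mode TinyFCN
  at 8 epochs, 7-fold participant-stratified CV, five seeds each: the
  median cross-validated AUC must reach 0.8 with `effect_size = 2.5` and
  stay within `[0.4, 0.6]` with `effect_size = 1`. The trip count matters
  for the null: with far fewer trips, chance cohort-level associations
  between the labels and kinematic covariates become learnable and push
  null AUC optimistically above chance, an effect that shrinks with the
  number of trips exactly as in real cohorts.
* **Sporadic-impairment demonstration.** `impaired_trip_fraction = 0.3`,
  5–12 trips per participant, ten seeds. Trip-level predictions come from a
  seeded emulator of a plausible trip classifier (sensitivity 0.75,
  specificity 0.90) applied to the generator's ground-truth impairment
  indicators — the property under test is the aggregation logic, namely
  that the 0.1 risk threshold flags strictly more true MCI drivers than the
  majority vote, in every seed.
* **Detector equivalence.** 200 generated trips with 1–5 planted corners;
  merged peaks must match the planted corners and a brute-force
  successive-heading-difference scan with precision and recall ≥ 0.9 at
  ±3 samples.

## Known limitations

* Synthetic validation only: absolute performance numbers on this generator
  say nothing about effect sizes in real drivers.
* The turn detector is threshold-based and intentionally simple; it does not
  classify turn type, infer intersections, or filter low-information
  maneuvers (shallow bends, stop-and-go creep), all of which are natural
  extensions.
* The recurrent families backpropagate through every timestep; on full
  1200-step trips they are markedly slower than the convolutional families
  and are most practical at turn-window lengths.
* Risk scores are computed from hard trip labels (the screening rule of the
  method); a probability-averaging variant is available via
  `risk_score(prob_column = )` but is not the default.
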
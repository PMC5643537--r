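---
title: "Linking EEG microstate dynamics to muscle synergies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking EEG microstate dynamics to muscle synergies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`microsyn` implements an analysis pipeline for multimodal recordings of
reaching-and-grasping movements: 64-channel EEG is segmented into
*microstates* (quasi-stable scalp topographies lasting tens of
milliseconds), 15-muscle EMG envelopes are decomposed into *muscle
synergies* (nonnegative weight vectors sharing a temporal activation),
and the window-wise occurrence of the two state alphabets is linked by
canonical correlation and a four-class linear-discriminant grasp
decoder. A synthetic-data generator with a full ground-truth answer key
makes every stage testable end to end.

This vignette documents the models, the tunable parameters, and the
design decisions that were genuinely open.

## The microstate model

EEG at each time sample is a channel vector (a scalp map). The
microstate model assumes the map series is piecewise stable: a small
alphabet of template maps, each active for 50–150 ms, with polarity
ignored (a map and its sign-flip are one state, because oscillatory
generators reverse polarity within a state).

**Clustering.** Maps are sampled at peaks of the global field power
(GFP, the spatial standard deviation of the map), where the
topographic signal-to-noise ratio is maximal. `modified_kmeans()`
clusters these maps with a polarity-invariant k-means: assignment
maximizes the *squared* spatial correlation to a template, and the
template update is the dominant eigenvector of the outer-product sum of
member maps — the exact polarity-invariant centroid once maps are
normalized to zero mean and unit norm (then correlation equals the
inner product). The best of `n_init` random restarts by explained
variance is kept.

**Model order.** `select_k()` scans K (default 2–8) and takes the
absolute minimum of the cross-validation criterion

\[ CV(K) = \hat\sigma^2 \left(\frac{C-1}{C-1-K}\right)^2, \]

where \(C\) is the channel count and \(\hat\sigma^2\) the mean residual
variance of maps after projection onto their assigned template. Only
the arg-min is consumed downstream, so any constant rescaling of the
criterion is irrelevant. Ties break toward smaller K (parsimony).

**Back-fitting and smoothing.** Every sample is labeled with the
template of highest absolute spatial correlation (`backfit()`);
zero-variance samples carry the previous label. Segments shorter than
23 ms are then rejected (`smooth_segmentation()`): offending samples
are absorbed into the neighboring state with the higher template
correlation, with a whole-run merge fallback that guarantees the
minimum-duration contract for any input.

**Matching.** Sets are matched across conditions (`match_sets()`) by
the optimal one-to-one assignment maximizing total absolute Pearson
correlation (exhaustive over permutations — sets never exceed ~8 maps);
pairs under 0.65 are reported unmatched. `group_cluster()` runs the
second-level clustering across subjects with the constraint that each
subject's maps occupy different clusters.

## The muscle synergy model

EMG envelopes \(V\) (muscles × time, nonnegative) are factorized as
\(V \approx WH\) with \(W \ge 0\) (muscles × K weights, unit-norm
columns) and \(H \ge 0\) (activations), by multiplicative-update NNMF
minimizing the squared Frobenius error. The problem is non-convex, so
each extraction is repeated 50 times from random starts and the restart
with the highest variance accounted for is kept. VAF is uncentered,

\[ \mathrm{VAF} = 1 - \|V - WH\|_F^2 / \|V\|_F^2, \]

the standard choice for rectified envelopes. The model order is the
smallest K with VAF > 98%. Synergies are matched by normalized scalar
products (DOT, threshold 0.65), and reference synergies are built by
agglomerative hierarchical clustering of pooled weight vectors
(Minkowski distance, order 2, average linkage) — the synergy
literature typically names the clustering without fixing metric order
or linkage; these defaults are the most common choices.

## Occurrence dynamics and statistics

The trial timeline is divided into 100-ms windows for movement
preparation (−2 s to movement onset) and holding (2 s), and windows of
10% of the movement duration for execution (20 + 10 + 20 = 50
windows). Per epoch and window the *prevalent* state is the one with
the most samples; ties go to the previous window's winner when it is
among the tied states, otherwise a seeded-random tied state. Occurrence
histograms are fractions of epochs per window (columns sum to 1).
Synergy occurrence is the Pearson correlation between the putative EMG
of one synergy (\(w_k h_k\)) and the observed EMG within the window,
averaged over epochs.

Condition contrasts use a permutation test with *epoch-level*
exchangeability: exchanging whole epochs between conditions preserves
the within-epoch dependence across windows and states that value-level
shuffling would destroy. The statistic is the per-state/per-window
occurrence difference, two-sided at α = 0.05, with no correction across
windows. With 15 epochs per side the test's discreteness makes it
conservative; a planted occupancy shift of 0.4 from a zero baseline is
reliably detected, while the same shift between mid-range occupancies
is near the detection boundary.

## Time-frequency analysis

`stft_power()` uses 200-ms Hamming windows with 32-ms steps (rounded to
whole samples at the working rate) and keeps 1–40 Hz.
`normalize_spectrogram()` expresses each frequency bin in percent
change relative to its own time-mean. The beta band is taken as
13–30 Hz. Movement-related beta desynchronization and post-grasp
rebound onsets are detected with a threshold/persistence rule (mean
beta change beyond ±10% sustained for 3 consecutive steps before
movement onset / after holding onset); the rule is this package's own —
the underlying studies report onsets without stating a detector — and
it carries an explicit one-step (32 ms) latency contract, verified on
planted square events.

## Canonical correlation and decoding

Per subject, microstate and synergy occurrence matrices are stacked
over tasks and phases into paired window × variable matrices
(`stack_occurrences()`); windows are aligned by their time stamps, so
the preparation phase contributes only the interval where both
occurrence definitions exist (synergy planning windows start at −1 s,
microstate windows at −2 s). `cca()` centers both sides, drops linearly
dependent columns (occurrence columns sum to 1, so one column per side
is always redundant) and returns canonical correlations with unit-norm
weight vectors. Component significance across subjects is a one-sided
Wilcoxon signed-rank test against matched row-permutation surrogates —
testing raw canonical correlations against zero would be degenerate
since they are nonnegative by construction.

The grasp decoder uses the preparation-phase occupancy one-hots
flattened to 20 windows × 5 states = 100 features. For each grasp and
repetition, a four-class LDA trains on half of that grasp's epochs plus
an equal count from each other grasp (class-stratified) and tests on
the held-out epochs of that grasp; 1000 repetitions are averaged. The
pooled covariance of one-hot features on tens of epochs is singular, so
the LDA shrinks it toward a scaled identity
(\((1-\lambda)S + \lambda\,\mathrm{tr}(S)/d\,I\), λ = 0.2 by default);
with λ → 0 it reproduces classic LDA on well-conditioned data (verified
against an independent solver). The significance level is the mean
accuracy under a label-shuffled null (≈25% for four balanced classes).
Note that when features *do* carry class structure, the shuffled-label
null of this held-out-one-class protocol sits slightly below nominal
chance; the calibration checks therefore use structure-free features.
Feature-set influence is removed by linear regression with intercept
(`residualize_features()`, idempotent), and coefficient stability is
the per-coefficient mean/SD ratio over repetitions against the 95th
percentile of the null ratios.

## The synthetic generator

The generator emulates the study's recordings with a known answer key:

* **EEG**: a first-order Markov chain over average-referenced,
  unit-norm topographies (pairwise |correlation| ≤ 0.5), geometric
  dwell truncated below 2 samples with 100-ms mean, multiplied by a
  positive GFP-like envelope (`0.5 + |sin|` at ~10 Hz so GFP peaks
  exist for peak-picking), plus white sensor noise at a configurable
  amplitude SNR (default 5). Four states are active at rest, five
  during tasks.
* **EMG**: nonnegative `W %*% H` from sparse ground-truth weights
  (each synergy dominated by three muscles) and sequential wide
  Gaussian activation bursts over a small tonic background — distinct
  burst centers keep the activation profiles linearly independent, so
  the factorization genuinely needs all K synergies, and the
  envelope-like duty cycle keeps 5%-of-peak noise at a realistic ~1% of
  signal power. Noise is clipped at zero.
* **Trial structure**: 5 tasks (pure reaching + 4 grasp types) × 15
  trials, each with `task_cue`, `movement_onset`, `holding_onset`,
  `release` events; ~2.5 s preparation, ~1.1 s movement (jittered),
  2 s holding.
* **Task coding**: each grasp biases the Markov chain toward a
  preferred state over the 20 preparation windows
  (`occupancy_separation`, default 3 — decodable well above chance but
  far from ceiling); microstate-synergy coupling multiplies synergy
  activations per 100-ms window by `1 + C[state, synergy] ·
  occupancy` (`coupling_strength`). With both at zero the dataset is
  null for CCA and decoding.

Signals are generated directly at the analysis rates (EEG 128 Hz, EMG
500 Hz); the preprocessing stages (zero-phase 1–40 Hz band-pass as
cascaded biquads, polyphase resampling, average reference, cubic-spline
epoch equalization, EMG detrend/50 Hz high-pass/rectify/10 Hz
low-pass/MVC scaling) are exercised on high-rate inputs in their own
tests. What the generator does **not** emulate: ocular or muscle
artifacts (the artifact-rejection hook is a simple ±100 µV amplitude
rule standing in for visual inspection), volume-conduction head-model
structure, and non-stationary noise — so passing tests demonstrate
parameter recovery under the stated model, not robustness to real-world
artifacts.

## Numerical choices and edge cases

* High-order Butterworth filters are applied as cascades of zero-phase
  biquads; the transfer-function form is unstable at 10 Hz/3 kHz-type
  relative cutoffs. The band-pass removes each channel's mean first,
  since the 1 Hz high-pass transient decays over seconds.
* NNMF multiplicative updates stop on a relative objective change below
  1e−6 or 500 iterations; denominators carry a 1e−12 guard. The
  objective trace is retained and asserted non-increasing.
* k-means re-seeds an emptied cluster at the worst-fit map; CV ties
  choose the smaller K; back-fitting labels zero-variance samples by
  carry-over.
* Pearson correlation on a zero-variance window is defined as 0 and
  counted in a degeneracy log.
* All assignment problems (map/synergy matching, group clustering) are
  solved exactly by exhaustive permutation — problem sizes never exceed
  ~8 per side.
* EDF/BDF export quantizes each channel over a symmetric physical range
  whose 8-character header representation is chosen to parse back
  exactly, bounding the round-trip error by half a quantization step.

## Problem sizes used in the checks

Model-order recovery runs 20–21 seeds of 60 s resting/task EEG at
128 Hz (SNR 5); synergy-count recovery uses single-trial movement EMG
(15 muscles × 5 s at 500 Hz, 5% noise) with 8–50 restarts; decoder
calibration uses 40 epochs per class and 1000 label-shuffled
repetitions (Monte-Carlo SE ≈ 0.3%). These sizes give stable majority
outcomes while keeping the full suite fast.

## Known limitations

* The CV criterion is implemented from its published form; absolute
  values may differ from other microstate toolboxes by a constant
  factor (harmless for model-order selection, which only uses the
  arg-min).
* The detector for beta events and the amplitude-threshold artifact
  rule are package-defined stand-ins for procedures that are manual or
  unspecified in the underlying literature.
* `synergy_occurrence()` assumes equal-length epochs when the model was
  fit to concatenated epochs.
* The pipeline treats synthetic EMG as envelopes; `process_emg()` is
  for raw recordings.
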
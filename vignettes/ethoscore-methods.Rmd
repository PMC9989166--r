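---
title: "Methods: pose-free aggression scoring and behavioral statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-free aggression scoring and behavioral statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoscore)
```

## Overview

`ethoscore` implements a complete analysis path for two standard rodent
behavioral assays:

1. **Resident–intruder (R-I) aggression scoring.** Top-view session videos are
   scored for physical attacks without any pose estimation. Frames are
   converted to grayscale and rebuilt as *temporal-difference channels*; a
   small convolutional binary classifier assigns each frame an attack
   probability; a moving-average/threshold peak-detection step bounds attack
   events; the session readout is the cumulative attack duration in seconds.
2. **Three-chamber sociability test (TCT).** Tracked three-point trajectories
   (nose, body center, tail base) are reduced to time spent in proximity of
   each stimulus cylinder (nose within 2.5 cm of the cylinder wall) and total
   locomotion (body-center path length).

A statistics layer provides the procedures used with such data: a zero-safe
log transform, Welch two-sample t-tests (from raw values or from published
mean ± SD summaries), a mixed two-way repeated-measures (split-plot) ANOVA
with genotype as the between-subject factor and treatment as the
within-subject factor, Tukey HSD and Sidak post-hoc adjustments.

Because raw recordings of this kind are rarely shareable, the package ships
synthetic-data generators for all three inputs. They are first-class, tested
code: every downstream stage can be exercised end-to-end without any
download.

## The frame classifier

### Input representation

Each frame is converted to grayscale with the ITU-R BT.601 luma weights
(0.299, 0.587, 0.114) — the standard convention for 8-bit video; any fixed
convention would do, but it must be fixed for reproducible inference. The
classifier input then replaces the three color channels with motion
channels:

* channel 1 — the current grayscale frame,
* channel 2 — current minus previous frame (lag 1),
* channel 3 — current minus the frame two steps back (lag 2).

Differences are signed and kept at full precision. Frames earlier than a lag
get a zero-filled channel, so the first frame of a video always has all-zero
difference channels. Two lags plus the current frame fill a three-channel
input analogous to the RGB layout they replace; the lags are configurable
through `training_config()`.

### Architecture and training

The default network is deliberately small: an initial 2×2 average pool
(64×64 → 32×32 — at the default blob scale of ~5 px this halves compute
without losing the animals), then three convolution blocks (8, 16, 32
filters, 3×3 kernels, ReLU, 2×2 max-pool), global average pooling, and a
single sigmoid unit. It is trained with Adam (learning rate 1e-3, batch 32,
10 epochs by default) on a weighted binary cross-entropy. The engine is
implemented natively in R on BLAS matrix products (im2col convolutions); its
gradients are verified against finite differences in the test suite.

Attack frames are rare (~1–2% of footage), so class imbalance is handled in
two stages: training frames are subsampled to all positives plus `neg_ratio`
(default 3) negatives per positive, and the residual imbalance is
compensated by a positive-class loss weight. Channels are normalized to
[−1, 1] using training-set statistics stored in the model, making inference
reproducible; a saved and reloaded model produces bit-identical
probabilities.

Validation follows a leave-one-video-out scheme: one training run per
held-out video, reporting the frame-level ROC AUC (Mann–Whitney formulation,
ties counted 1/2) on the held-out video. A held-out video that contains no
attack frame has no defined AUC and is reported as `NA`; the summary is the
mean over defined folds. All stochastic steps derive from the single
`training_config()` seed.

### Operating threshold

Two selection rules are provided:

* `select_specificity_threshold()` returns the most sensitive threshold
  subject to a specificity floor. For rare events a floor must be strict:
  at ~1% prevalence a 1% false-positive rate produces about as many false
  alarm frames as true attack frames, so the default floor is 0.999. This
  operating point deliberately under-detects — the cost of suppressing false
  positives is reduced sensitivity.
* `select_duration_threshold()` scans candidate thresholds and picks the one
  whose detected total duration best reproduces the reference (ground-truth
  or human-scored) cumulative attack duration on the training sessions, with
  ties resolved toward the higher threshold. This is the right operating
  point when the readout of interest is duration itself, and it is what
  `run_pipeline()` uses by default.

## Event bounding

`detect_events()` applies three rules, in a fixed order, to the smoothed
probability trace:

1. maximal runs of frames strictly above the threshold become candidates;
2. candidates separated by at most `merge_gap` frames are merged;
3. merged candidates shorter than `min_duration` frames are discarded.

Merging precedes the duration filter so that a bout fragmented by a brief
probability dip is not discarded piecewise. Intervals are 0-based and
closed, matching the per-frame labels, so an event's duration is exactly
`end − start + 1` frames. The smoothing window (default 5 frames) uses a
centered mean that shrinks at the trace edges. Defaults for the other knobs
are expressed in time and converted at the session frame rate: merge gap
0.5 s, minimum duration 0.3 s. The strict `>` threshold rule makes tie
behavior at the threshold deterministic.

`event_match_metrics()` quantifies agreement with reference scoring: a
predicted event matches a truth event when it covers at least half of it
(configurable), matching is one-to-one and greedy in temporal order, and the
conventions for empty sets are precision = 1 with no predictions, recall = 1
with no truth.

## Three-chamber readouts

The arena is 40.5 × 60 cm, split into three compartments along the long
axis, with one wired cylinder (radius 5 cm) centered in each lateral
compartment. "Within 2.5 cm of the cylinder" is interpreted as within 2.5 cm
of the cylinder *wall* — a 2.5 cm ball around the center would lie inside
the cylinder and be unreachable — so a sample counts when the nose is at
most 7.5 cm from the cylinder center, boundary inclusive. Each sample
contributes its preceding inter-sample interval to the dwell sum (a left
Riemann convention, stated explicitly because trackers differ); missing
samples are dropped, and path segments with a missing endpoint are skipped
rather than interpolated. Locomotion is the summed Euclidean length of the
body-center path. Stimulus-side assignment (which cylinder holds the
stimulus mouse vs the object, or the familiar vs the unfamiliar mouse) is a
pure relabeling of the per-cylinder times and supports the counterbalanced
design.

## Statistics

* **Zero-safe log transform.** Attack durations are log transformed before
  testing; sessions with no attack score exactly 0. With zeros present the
  constant `c = sqrt(Q1/Q3)` is added first (quartiles of the full value set
  by linear interpolation, the common default convention). The published
  phrasing of this constant is ambiguous between `sqrt(Q1/Q3)` and
  `sqrt(Q1)/Q3`; the ratio reading is adopted because it is dimensionally
  sensible (the constant then scales with the data), and the constant used
  is always reported in the result object. The natural log is used; the
  base does not affect any t or F statistic. A degenerate `Q1 = 0` falls
  back to half the smallest positive value, with a warning.
* **Welch t-tests.** The unequal-variance statistic with Welch–Satterthwaite
  degrees of freedom, two-sided p-values; computable from raw vectors or
  from mean ± SD ± n summaries (the two agree exactly when the summaries
  come from the same data). Non-integer published degrees of freedom (25.5,
  29.7, 31.1) identify the Welch form.
* **Mixed two-way RM ANOVA.** Classic split-plot decomposition: genotype is
  tested against subjects-within-genotype, treatment and the interaction
  against the within-subject residual. Subjects missing a within-level are
  dropped (complete-case), and the dropped count is reported — classical RM
  ANOVA requires complete within-subject data. Unequal group sizes are
  handled with weighted (sequential) sums of squares, which for a complete
  within-subject design coincide with R's `aov()` multi-stratum output (the
  test suite checks this equivalence on random unbalanced designs).
* **Post-hocs.** Tukey HSD over the four genotype × treatment cell means
  uses the studentized-range distribution with Tukey–Kramer standard errors;
  comparisons differing in treatment use the within-subject residual mean
  square, comparisons differing only in genotype use the between-subject
  error, the standard split-plot practice. Sidak adjustment is
  `1 − (1 − p)^m`. With two groups the Tukey-adjusted p equals the
  unadjusted p. Two-sided tests and α = 0.05 throughout.

## What the synthetic generators emulate — and what they do not

**R-I videos** (`simulate_ri_video()`): two soft-edged discs — a light
resident (intensity 230) and a dark intruder (40) on a mid background
(130) — perform independent bounded random walks with reflecting walls.
Attack bouts arrive as a thinned Poisson process (default 0.5 bouts/min,
1–3 s each, so ~1.7% of frames are attack-labeled, matching the order of
prevalence in real recordings); during a bout the intruder stays within the
contact distance of the resident and both receive high-frequency jitter.
Because real training recordings are *selected* for containing aggression,
the default schedule is conditioned on at least one bout per session
(`min_bouts = 1`; set 0 for the unconditioned process). The generator
returns exact ground-truth intervals, frame labels and true blob centers.
Camera resolution and frame rate of the original recordings are not
published; the 64×64 px / 15 fps defaults are configurable choices, not
reconstructions.

What it does **not** model: coat texture, body articulation, occlusion,
illumination changes, non-attack aggressive displays (lateral threats,
offensive uprights). A high hold-out AUC on this generator therefore shows
that the pipeline learns motion-plus-proximity signatures as designed — it
does not certify performance on real videos.

**TCT trajectories** (`simulate_tct_session()`): a waypoint walk alternating
travel segments with orbiting dwells just outside a cylinder wall. Which
cylinder is visited is chosen by a deficit scheduler so realized dwell times
track the configured `preference_weights` with low variance (a biased
random walk would need far longer sessions for stable preferences). The
default speed of 6 cm/s yields ~3,500 cm locomotion per 10-min phase, the
magnitude seen in real sessions. Nose and tail base are placed 2 cm ahead
of / 2.5 cm behind the body center along the heading.

**Cohort tables** (`simulate_cohort()`): lognormal attack durations with
additive log-scale genotype and treatment effects, a between-subject random
intercept, session noise, exact zeros injected with probability
`zero_prob`, and clamping to the 600 s session length. The design mirrors a
longitudinal study: monthly sessions, with a final-age vehicle/drug
cross-over in which every animal is tested under both treatments.

## Numerical and design choices

* Determinism: every generator and every training run is a pure function of
  its parameters and seed; the global RNG state of the caller is left
  untouched. A pipeline seed fans out to stage seeds by fixed offsets.
* Problem sizes: validation runs in the test suite use eight 2-minute
  64×64 px sessions for the leave-one-out study and 10-minute sessions for
  event recovery; the type-I error of the ANOVA and Welch tests is
  calibrated on 2,000 null cohorts (n = 10 per genotype), and transform-side
  power on 2,000 effect cohorts. These sizes give Monte-Carlo standard
  errors comfortably inside the asserted tolerances.
* Null calibration uses `zero_prob = 0` (the continuous regime): after the
  log transform the null distribution is exactly normal, so the 5% level is
  exact and deviations indicate implementation error rather than model
  misfit. With zeros injected, the transform's point mass makes the nominal
  level only approximate — that regime is exercised elsewhere in the suite.
* Video serialization uses lossless multi-frame 8-bit TIFF with a JSON
  sidecar for frame rate and labels. A lossy or codec-dependent container
  would break the bit-identical round-trip contract the tests enforce.
* Degenerate inputs: both-variance-zero Welch tests, single-class ROC
  inputs, all-zero transforms, single-sample path lengths and empty event
  sets all have explicit, tested behaviors (error, warning, or defined
  convention) rather than silent NaNs.

## Known limitations

* The classifier engine is CPU-bound, single-threaded R; it is sized for
  small behavioral models (tens of thousands of parameters), not for
  transfer learning or large backbones.
* Event bounding assumes the probability trace is already well calibrated;
  systematically biased probabilities shift the duration-calibrated
  threshold but are not corrected for.
* The split-plot ANOVA covers one between- and one within-subject factor
  with two or more levels each; sphericity corrections are unnecessary for
  the two-level within factor used here and are not implemented.
* Proximity zones are circular; trackers that draw polygonal zones will
  differ slightly near the compartment walls.
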
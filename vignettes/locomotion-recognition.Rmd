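---
title: "Two-layer DTW locomotion recognition: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer DTW locomotion recognition: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdtw)
```

## The recognition model

`gaitdtw` classifies every frame of a six-axis lower-back IMU recording
(100 Hz; `AccX`/`AccY`/`AccZ` in m/s², `GyroX`/`GyroY`/`GyroZ` in °/s;
z vertical, y mediolateral, x anterior-posterior) as walking, ascending
stairs, descending stairs, or none of these.  The underlying assumption
is that locomotion is quasi-periodic: one stride — left heel strike to
the next left heel strike — is a unit whose overall shape is stable
within an activity, while its duration, amplitude and internal timing
vary.  Dynamic time warping (DTW) is the natural comparison under that
assumption: it finds the monotone alignment of two sequences that
minimizes the accumulated sum of absolute sample differences (called
*ED* throughout), absorbing timing variability that a rigid Euclidean
comparison would punish.

DTW here uses the three classic steps (advance query, advance template,
advance both), full boundary conditions, and absolute difference as the
local cost; the accumulated distance counts each path pair once.  Two
choices deserve a note:

* **No length normalization.**  The distance thresholds of layer 2 are
  interpreted as raw accumulated distances; normalizing by path length
  would silently change their meaning.
* **Deterministic tie-breaking.**  Equal-cost dynamic-programming cells
  prefer the diagonal step, then query-advance, then template-advance.
  Ties are measure-zero on real signals but must be reproducible.

## Template construction

Per activity and axis, stride snippets are averaged by DTW barycenter
averaging (`dba_average()`).  The procedure is made fully deterministic:
initialization is the *medoid* snippet (smallest sum of DTW distances to
the rest, first on ties), resampled to the target length by linear
interpolation — snippets themselves are never resampled, since DTW
handles length differences.  Each iteration aligns every snippet to the
current average and replaces each average sample by the mean of the
snippet samples aligned to it.

The mean update is the classical DBA step; under the absolute-difference
local cost it is a heuristic rather than the exact per-sample minimizer
(that would be the median).  The implementation therefore evaluates the
objective (mean DTW distance to the average) before every update and
returns the last iterate whose objective was evaluated, stopping as soon
as the improvement falls below `tol` (default 1e-6) or an update would
increase the objective.  The recorded objective trace is consequently
non-increasing by construction, which the test suite asserts on seeded
snippet sets.

The reference length of an activity is the median snippet length,
rounded — robust against occasional outlier strides; the median of
typical stride databases differs from the mean by at most a frame or
two, and any fixed rule is acceptable as long as it is deterministic.

## Layer 1: sliding-window matching

The matcher (`sliding_match()`) slides a window of
`window_factor = 1.5` reference lengths, so even unusually long strides
fit inside one window.  A window is refined (`refine_and_score()`) by
aligning it to the template and finding *stretched areas* of the warping
path: maximal runs in which one template frame absorbs consecutive query
frames.  Runs of at least `stretch_min_fraction = 0.10` of the reference
length mark surplus signal; their borders become candidate new window
borders.  Two implementation details:

* A run of length one is no repetition, so the minimum qualifying run is
  `max(2, ceiling(fraction × reference length))`; a pure diagonal path
  yields no regions at any template length.
* The first pair of a run is simultaneously the end of a genuine match
  and the start of the stretch, so *both* sides of each region border
  are offered as cut points.  With only one side, a window consisting of
  the template plus trailing padding is trimmed one frame short of the
  true border.

All candidate sub-windows at least `min_window_fraction = 0.40` of the
reference length (shorter events are implausible) are re-aligned and the
smallest distance wins; ties go to the earliest start, then the shortest
section, and the untrimmed window is always a fallback, so refinement can
never worsen the distance.  Note that refinement is not guaranteed to
find the globally best sub-window: the optimal full-window path of a
window straddling two stride copies can stall mid-template, leaving a
small residual distance where an exhaustive sub-window search would find
zero.  The residual is far below any realistic threshold and disappears
once windows advance past the join.

The next window starts at the found section's end minus
`overlap_fraction = 0.25` of the reference length (the overlap is
measured against the reference length, not the matched section, so the
step size does not depend on match quality).  Gaps between stored
sections are then closed: gaps of 25–75% of the reference length are
re-matched as one window; gaps under 25% inherit the bordering section
with the smaller distance; gaps above 75% — not covered by the two
published gap rules — simply re-enter the sliding loop, which guarantees
that every frame eventually carries a distance.  Wherever assignments
overlap, the smallest distance always wins.

## Layer 2: probabilities and classification

Distances become probabilities through
`P = 101 − 101^(ED/threshold)` for `ED < threshold`, else 0
(`frame_probability()`).  This functional form is fixed by its two
anchors: a perfect match gives exactly 100, and the probability falls
continuously and strictly to 0 at the threshold.  Equality with the
threshold yields 0 from the formula itself, so no separate strictness
convention is needed.

The per-axis probabilities of an activity are combined
(`combine_axes()`) by a weighted arithmetic mean — the operator that
preserves the 0–100 scale and both published special cases — over the
activity's axis selection (`default_axis_config()`): `AccX` and `AccZ`
for every activity, plus the gyroscope axes that discriminate it.  The
vertical accelerometer axis is weighted double for walking only, where
it is the dominant single-axis discriminator; the weighting is
configurable per activity.  If at least `zero_axes_cutoff = 3` axes show
probability 0, the combined probability is 0.

Sections shorter than `length_cutoff_fraction = 0.5` of the reference
length are penalized by `f = 2 × section length / reference length`
(`length_penalty()`); the "activity length" entering the rule is the
matched section's length in frames.  Because each axis can assign a
different section to a frame, the per-frame section length entering the
penalty is the median over the activity's used axes — deterministic and
robust to one axis fragmenting.  Finally `classify_frames()` takes the
per-frame arg-max with the fixed tie order walking, ascending, then
descending stairs, and labels frames with all-zero probabilities
`no_selected_activity`.

The published threshold table (`default_thresholds()`) applies to 100 Hz
lower-back recordings in the stated units; it is configuration, not a
constant.  For any other source — synthetic data in particular — use
`derive_thresholds()` (see below).

## Preprocessing

`rotate_axes()` brings arbitrary mounting conventions onto the canonical
axis frame (permutations with sign flips; accelerometer and gyroscope
families may not mix).  `correct_standing_offset()` compares the mean of
the accelerometer channels over labelled standing phases against the
nominal standing values (0, 0, 9.81 m/s²) and shifts each channel by the
difference; it is idempotent and leaves the gyroscope untouched (no bias
reference exists for it in standing).  The correction takes explicit
standing intervals, leaving per-session versus pooled grouping to the
caller.  The loader rejects missing and non-finite samples rather than
interpolating: implausible segments should be excluded, not repaired.

## The synthetic generator

`generate_recording()` emulates the structure this pipeline faces in
free-living data: locomotion bouts interleaved with standing (static
gravity vector) and sitting (gravity tilted forward by 20°), with exact
ground-truth labels and stride boundaries.  Strides are sums of 2–3 low-
order harmonics per axis with distinct amplitude ratios and cadence per
class — vertical amplitude grows from walking (2.0 m/s²) through stair
ascent (3.2) to descent (4.2), ascent is slowest (1.4 s mean stride
versus 1.1/1.2 s) — deliberately *partially* overlapping on the
mediolateral and gyroscope axes so the misclassification paths between
walking and stair climbing stay exercisable.  Per-stride duration
(truncated Gaussian), a per-stride amplitude factor (sd 10%), and white
noise (0.15 m/s² / 2 °/s during movement) supply the variability DTW is
meant to absorb.  The default schedule is a 10-minute mixture with stair
bouts much shorter than walking bouts.

What the generator does **not** model: turning, shuffling and postural
transitions, soft-tissue artefacts, sensor drift, or the biomechanical
asymmetries of real gait.  Passing the synthetic end-to-end bar
therefore demonstrates that the algorithmic machinery (windowing,
refinement, gap closure, thresholds, axis combination) works as
specified — it does not certify recognition rates on real recordings,
whose published values stem from a video-validated free-living dataset.

`apply_tilt()` rotates the accelerometer and gyroscope vectors about the
body axes (`R = Rz·Ry·Rx`) for misplacement-robustness experiments; the
intended range is small angles (up to ~30°), but no bound is enforced so
rotations compose exactly.

**Thresholds for synthetic data.**  `derive_thresholds()` defaults to
the 95th percentile of the per-frame distances that the layer-1 matcher
itself produces on the calibration recording's own-class intervals.
Calibrating on matcher output (rather than on stride-snippet distances,
also available as `method = "snippet"`) mirrors how the operating
thresholds were originally determined — from recognition performance on
development data — and automatically absorbs the distance inflation that
window phase and refinement imperfections add on top of snippet-level
variability.  The quantile is fixed at 0.95: about 5% of own-class
frames fall above their axis threshold, which the ≥3-zero-axes rule then
converts into occasional unassigned frames rather than misses.

## Problem sizes and numerical choices

The packaged validation uses 10-minute recordings (60,000 frames),
templates built from at most 140 strides per activity (an evenly spaced,
deterministic subsample comparable to a realistic manually-cut stride
database), and DBA at up to 30 iterations with `tol = 1e-6`.  Distance
comparisons against fractional cutoffs use a 1e-9 guard so that exact
products (e.g. 10% of a 100-frame template) are not lost to floating
point.  Degenerate inputs are handled explicitly: a template longer than
the signal is matched as a single short window; an all-static signal
still receives full distance coverage; empty snippet lists, empty
standing references and schedule errors fail fast with named messages.

## Known limitations

* Thresholds do not transfer across units, sampling rates or
  populations; re-derivation is mandatory for new data sources.
* Window refinement inspects only stretch-region borders; it is a
  heuristic for the best sub-window, not an exhaustive search.
* Evaluation is frame-level only; event-level (bout) metrics are out of
  scope.
* The three-class vocabulary is fixed; adding activities means adding
  templates, thresholds and axis selections.
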
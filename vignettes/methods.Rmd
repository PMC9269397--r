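---
title: "Multimodal posture classification and MET-based energy expenditure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal posture classification and MET-based energy expenditure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metfuse)
```

## The problem

Objective quantification of physical-activity energy expenditure (EE) in
ambient-assisted-living settings calls for sensors that are cheap,
unobtrusive and redundant: a camera loses the subject behind furniture, a
wearable is worn incorrectly or left on a table. `metfuse` implements a
two-branch pipeline over a chest-worn tri-axial accelerometer and an
ambient depth camera, classifies seven activity classes — standing,
sitting, bending, lying, and walking in three speed bands (< 1.5,
1.5–3.0, 3.0–4.5 km/h) — at 1 Hz, and converts the label stream into
kilocalories through a MET lookup.

## Energy model

A MET (metabolic equivalent of task) is the resting energy cost,
1 kcal·kg⁻¹·h⁻¹, equivalently 3.5 mL O₂·kg⁻¹·min⁻¹. Each activity class
carries a fixed MET value (packaged defaults: standing 1.2, sitting 1.0,
bending 0.9, lying 1.0, walking 1.9 / 2.6 / 3.4 by speed band). EE
accumulates per classification tick as

$$\mathrm{EE} \mathrel{+}= 3.5 \cdot \mathrm{MET}(a_i) \cdot \frac{w}{200} \cdot \frac{\Delta t_i}{60\,\mathrm{s}} \quad [\mathrm{kcal}],$$

with $w$ the body weight in kg and $\Delta t_i$ the tick duration
(default 1 s; a per-minute accumulation loop is the $\Delta t = 60$ s
special case). The per-minute rate $3.5 \cdot \mathrm{MET} \cdot w/200$
is the standard oxygen-uptake-derived approximation; for a 75 kg subject
walking 18 min at MET 2.6 it gives 61.425 kcal. Reference values for
whole protocols are printed truncated to two decimals, so comparisons to
printed EE use a 0.01 kcal tolerance. Only activity EE is modelled:
basal metabolism and the thermic effect of food are out of scope, as is
calorimetric ground truth.

The MET table is configuration, not a constant: compendium revisions or
population-specific values can be swapped in (`met_table()`), with the
only structural constraints that values are positive and walking METs
increase with the speed band.

## Wearable branch

The accelerometer is chest-worn, 50 Hz, ±2 g, with the trunk-aligned
axis y (standing reads ≈ (0, +1, 0) g). The branch proceeds:

1. **Calibration** (30 s of quiet standing): the per-axis mean becomes
   the static baseline. If any axis deviates from (0, 1, 0) g by more
   than 0.2 g, the device is flagged as worn incorrectly and feature
   extraction is blocked. The tolerance and expected orientation are
   configurable — they are deployment conventions, not physical
   constants.
2. **Pre-processing**: an order-8 (9-tap) linear-phase FIR low-pass at
   10 Hz, designed by the Hamming-window method and normalised to exact
   unity DC gain so posture (gravity) information is untouched. The
   filter is applied single-pass with reflected edge padding and the
   4-sample group delay removed, so output aligns with input timestamps
   and the effective magnitude response is the designed $|H(f)|$ (a
   forward–backward application would square it). Timestamp jitter
   beyond 10 % of the median interval is rejected rather than silently
   resampled.
3. **Sliding windows**: 300 ms length, 50 ms hop (15 samples advancing
   by 2.5 samples' worth of time at 50 Hz); a trailing partial window is
   discarded.
4. **Features** (6 per axis, 18 total, axis-major order): mean (g),
   energy (mean square, g²), *dynamic variation* — the population
   standard deviation of the mean-removed window (the AC, movement
   component), *static variation* — the absolute deviation of the window
   mean from the calibration baseline (the DC, orientation component),
   excess kurtosis and Fisher–Pearson skewness. The static/dynamic split
   mirrors what a DC-coupled accelerometer actually measures: gravity
   orientation plus movement. Population (biased) moments are used
   throughout so the four central-moment features are mutually
   consistent; when the per-axis standard deviation is below 1e-8 g the
   two shape features are defined as 0 (a constant window has no shape).

## Ambient branch

An upstream pose detector (out of scope here) supplies, per frame, 33
landmarks as pixel coordinates with per-landmark depth. The branch
deprojects them through the pinhole model
($x = (u-c_x)\,d/f_x$, $y = (v-c_y)\,d/f_y$, $z = d$; camera frame
x right, y down, z forward) and keeps three landmark-pair midpoints:
mouth (9, 10), hips (23, 24) and knees (25, 26), plus the subject
height — ten features. Midpoints of bilateral pairs cancel lateral
asymmetry and halve landmark noise; mouth, hip and knee heights and
anterior offsets are close to sufficient statistics for the four static
postures.

Height can come from the subject profile (default) or from the vertical
extent of a standing frame (`estimate_height()`); which source the
original platform used is not documented, so both are exposed. A
non-positive depth marks a landmark invisible rather than erroring;
frames whose required pairs are occluded raise a typed
`occlusion_error` (per-frame API) or yield NA rows (stream API), which
the fusion stage consumes as a missing-modality signal.

## Fusion, classifiers, cross-validation

Fusion is at feature level: the 18 wearable features followed by the 10
ambient features, a fixed ordering embedded in persisted model bundles.
Classification happens per wearable window (the nearest ambient frame
within half a frame period supplies the ambient block); window labels
are majority-voted into 1 Hz ticks, ties broken by the most recent
window. When the ambient block is missing (occlusion) the wearable-only
fallback model classifies the window, and vice versa; with both missing
the second is a gap and contributes no EE. Decision-level fusion is
deliberately not implemented: a missing sensor starves a decision-fusion
rule, whereas feature-level fallback degrades gracefully.

Fixed hyperparameters: fused random forest 25 trees / depth cap 30
(standalone wearable forest 29 / 26; the caps exceed any depth reachable
at these training sizes, so trees effectively grow to purity — the
`randomForest` backend exposes no direct depth parameter and a node-count
guard enforces the cap only when it could bind); ambient SVM with
polynomial kernel of degree 3 and kernel coefficient γ = 0.61; fused SVM
degree 3 with γ = 1/28; KNN with 13 neighbours, Minkowski power 2
(Euclidean). SVM and KNN inputs are standardised with statistics from
the training folds only. Two numerical choices deserve note. First, the
polynomial offset (coef0) defaults to 1: with standardised, mean-zero
features a zero-offset degree-3 kernel spans only odd homogeneous
cubics and cannot represent magnitude-type boundaries such as "trunk
lean larger than x irrespective of walking direction". Second, the
configured SVM iteration cap (50) is recorded in the configuration for
provenance, but the libsvm backend iterates to its tolerance;
standardisation keeps convergence fast, and the cap is not enforced
mid-optimisation.

Cross-validation follows an 80/10/10 rotation: ten stratified folds; in
rotation $r$ fold $r$ is the test set, the next fold is held out for
validation (reserved for threshold/seed selection, otherwise unused) and
the remaining eight folds train. Every sample is tested exactly once;
test-fold confusion matrices are pooled. Whether the original scheme
rotated validation and test folds jointly or nested them is not
documented; this is one consistent reading. Folds are stratified over
pooled windows; subject-wise splitting is not the default because the
reference evaluation pooled all users.

Metrics are multiclass accuracy (diagonal share of the confusion
matrix), Cohen's kappa $k = (p_o - p_e)/(1 - p_e)$ with the usual
agreement bands, and the EE relative error
$|EE_{gt} - EE_{est}|/EE_{gt} \times 100$. The published band table
leaves the decade boundaries uncovered (e.g. [0.40, 0.41)); bands are
implemented half-open — slight < 0.20 ≤ fair < 0.40 ≤ moderate < 0.60 ≤
good < 0.80 ≤ perfect ≤ 1 — and kappa is reported raw (it can be
negative under worse-than-chance agreement; such values band as slight).

## Synthetic data generators

No recordings are distributable, so seeded generators stand in for the
devices; every generator is a pure function of its arguments and seed
and restores the caller's RNG state.

**Accelerometer.** Each class has a mean chest orientation (a trunk
pitch rotated gravity vector), Gaussian tremor (σ 0.015 g static,
0.03 g walking), and, for walking, a sinusoid on the trunk axis at the
class step frequency with a weaker quadrature anterior component.
Defaults: step frequencies 1.2 / 1.6 / 1.9 Hz and amplitudes
0.05 / 0.12 / 0.25 g for the three speed bands, placing the
dynamic-variation feature in distinct but tail-overlapping ranges.
Standing and sitting differ only by a 7° trunk-pitch offset, so the
wearable branch finds them genuinely confusable — the qualitative
weakness the camera compensates. Pitch values (bending 50°, lying 87°)
and tremor levels are generator conventions chosen to be
anthropometrically plausible, not measured constants.

**Skeleton.** A 33-landmark template in a body frame scaled by stature
(standing vertical extent ≈ 0.96 × stature), posed per class: sitting
drops the pelvis to seat height with horizontal thighs; bending pitches
the trunk 65° about the hip line; lying lays the body along the lateral
axis at bed height (vertical extent < 0.3 m). Walking leans the trunk
3 / 7 / 12° with speed, translates the body across the field of view in
a ping-pong path at the band's midpoint speed, and adds vertical bob at
twice the step frequency (15 / 35 / 65 mm) with alternating knee lift
(30 / 70 / 120 mm) — magnitudes in the range gait studies report for
slow-to-moderate walking, increasing with speed. Frames are projected
through a pinhole camera (defaults fx = fy = 600 px, principal point
(424, 240), approximating an 848×480 depth stream — configurable and
never claimed to be any particular device's calibration) mounted at
1.43 m, then corrupted with 0.5 px landmark jitter and 1 % multiplicative
depth noise (the error class of consumer stereo-depth cameras).
Occlusion episodes hide the hip and knee landmarks during sitting
(chair-behind-a-desk scenario): each second an episode starts with
probability `occlusion_rate` (default 0.02) and lasts 3 s, so a rate of
1 yields continuous occlusion.

**What the generators do not emulate**: pose-detector failure modes
(identity swaps, jitter bursts, systematic depth bias at silhouette
edges), accelerometer drift and temperature effects, gait harmonics and
heel-strike transients, or inter-subject gait style variation beyond
stature scaling. Passing tests therefore demonstrate that the pipeline
machinery is correct and that the advertised accuracy/EE bounds hold
under this signal model — not that they would hold on any particular
recorded data set.

**Training corpus.** `gen_training_corpus()` simulates 12 short bouts
per class, each with a fresh stature (uniform 1.50–1.90 m), starting
position, walking direction and gait phase, and returns exactly
`n_per_class` aligned wearable/ambient/fused vectors per class. The bout
count matters: with only a handful of bouts per class, bout-level
nuisance factors (absolute position along the walking path, the
particular stature draws) correlate spuriously with the class label and
classifiers learn them; a dozen independent bouts per class decorrelates
them. Walking speed is taken as the band midpoint — the smartwatch speed
feedback the original protocol gave its participants has no synthetic
counterpart.

## Problem sizes and numerical conventions

The packaged evaluations use: training corpora of 60–100 vectors per
class; the three scripted protocols (7, 7 and 6 minutes) over the
11-subject cohort (weights 52–83 kg, heights derived from weight and
BMI since stature is not part of the cohort table); and per-protocol
cross-validation corpora of up to 1000 windows per class pooled from
three simulated executions. These sizes were chosen so a full run
completes on a single desktop core in well under an hour while keeping
every class represented in every fold. Seeds are fixed throughout;
repeated runs are byte-identical.

One protocol's published ground-truth EE column is internally
inconsistent with the packaged protocol and MET tables (segment-wise
MET-minutes give ≈ 12.15 for protocol 2, while the printed values imply
≈ 13.25); the discrepancy is documented and protocol 2 is excluded from
numeric EE comparisons, which is why reference checks use protocols 1
and 3 only.

## Known limitations

- The ambient branch encodes no explicit velocity; walking-speed
  information reaches it only through posture correlates (lean, bob,
  knee lift). Plain Euclidean KNN on the fused vectors consequently
  confuses adjacent speed bands more than the forest or SVM do, and is
  the weakest of the three fused classifiers here (matching the
  published ranking, where KNN is also last).
- Majority voting to 1 Hz assumes the subject holds an activity for the
  better part of a second; sub-second transitions are not representable.
- The EE model inherits every limitation of MET-based estimation:
  population-average intensity values, no individual fitness adjustment,
  and no basal component.
- Calibration assumes quiet standing; a subject who cannot stand still
  for 30 s needs a different calibration posture and baseline.
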
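---
title: "Methods: from keypoint tables to a locomotor profile"
author: "gaitprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from keypoint tables to a locomotor profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitprofiler)
```

`gaitprofiler` post-processes markerless keypoint tracking of mice crossing
a runway or an irregular horizontal ladder, recorded simultaneously from
the left, right and bottom (three 2-D views sharing one frame clock). This
vignette explains the measurement model stage by stage, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the underlying
definitions left room.

## Input model and quality control

The input dialect is the DeepLabCut CSV: three header rows (scorer,
bodyparts, coords) and per-bodypart `x`, `y`, `likelihood` columns, one
row per frame. Side views track 10 landmarks (head, front toe tip, wrist,
shoulder, elbow, back toe, back ankle, iliac crest, hip, tail), the bottom
view 8 (head, left/right front toes, centre front, left/right back toes,
centre back, tail base).

Three conventions matter everywhere downstream:

* **Calibration.** 1 cm = 37.79528 px and 60 frames = 1 s by default
  (`gait_calibration()`); a config may override `px_per_cm` per view,
  since a mirror-based bottom view need not share the side-view
  calibration.
* **Masking, not imputation.** Frames whose detection likelihood falls
  below 0.95 are excluded (`filter_likelihood()`), and excluded frames
  propagate as gaps: speeds next to a gap are undefined, phase tracks mark
  the frame `invalid`, per-cycle statistics skip it. Nothing is ever
  interpolated, because an interpolated paw position would silently invent
  kinematics. Filtering is idempotent and monotone in the threshold.
* **Orientation.** Image y grows downward, so all heights are computed as
  `(ground_y − y) / px_per_cm` with the floor reference `ground_y` taken as
  the per-run lowest point (largest image y) of a toe-tip track — toes
  touch the floor, so their lowest tracked point is the best available
  floor estimate. Runs are mirrored so travel is always towards +x
  (`normalize_direction()`, decided by the net displacement of the tail
  base or head), which makes protraction (+x) and left/right sign
  conventions reproducible across runs recorded in either direction.

Tracking quality against human annotations is summarized by
`label_rmse()` (per-bodypart root-mean-squared Euclidean pixel error) and
`confident_label_ratio()` (fraction of labels within 17 px ≈ 0.45 cm of
the ground truth).

## Step segmentation

Paw speed is the frame-to-frame horizontal displacement scaled to cm/s. A
frame is **swing** when the speed exceeds 10 cm/s, **stance** otherwise.
Two debouncing choices are ours (the threshold rule alone says nothing
about jitter): the speed is median-smoothed over 3 frames, and phases
shorter than 3 frames are merged into their longer neighbour. At 60 fps a
3-frame rule removes single-frame tracker jitter while leaving real
phases (≥ ~100 ms in walking mice) untouched. Both windows are arguments
of `classify_phases()`; setting them to 1 reduces the operation to exact
thresholding, which is how the oracle tests pin it down.

A **step cycle** spans one stance onset (swing→stance transition) to the
next. Leading fragments are dropped: a recording that begins mid-stance
cannot be distinguished from one that begins exactly at an onset, so the
first usable onset is the first observed swing→stance transition. Cycles
whose interior is not one stance run followed by one swing run (after
masking) are discarded rather than guessed at.

From the cycles: durations (frames / fps; stance + swing = cycle by
construction), duty cycle (stance/cycle), and stride length (mean |Δx| of
the paw between successive stance onsets). Side-view per-step statistics
reuse the bottom-view cycles of the same side's paws — the views share the
frame clock — and fall back to segmenting the side-view toe with the same
10 cm/s rule when no bottom view exists. Side-view step windows run from
onset to next onset *inclusive*, so a step's net displacement covers
exactly one cycle of motion.

## Diagonal synchronization

In a coordinated walk the diagonal pairs (front-left with back-right,
front-right with back-left) plant together. Per pair, frames where both
paws are in stance count as synchronized (`totalSync`); frames where
exactly one is in stance count as unsynchronized (`totalNotSync`); the
asynchrony ratio is `1 − totalSync/(totalSync + totalNotSync)`. Frames
where both paws swing are not tallied: they carry no information about
*stance* coordination, and counting them would report an asynchrony of
1 − duty even for a perfectly locked gait. Under this reading a pair
whose cycles are offset by a fraction δ at duty d has the closed-form
asynchrony `(2d − 2v)/(2d − v)` with `v` the circular overlap of the two
stance arcs (`analytic_asynchrony()`), which is what the simulator-based
tests recover. Offsets smaller than ~2 frames of phase are at the
sampling resolution limit (1/fps) and alias; recovery is validated at
offsets of 3 frames and more.

## Side-view parameters

Per step and joint: mean relative height and total vertical movement
(highest minus lowest height), net horizontal step length and total
horizontal movement, all averaged over cycles and reported in cm. Note
that a max − min range is upward-biased under tracker noise: with 2 px
i.i.d. noise the expected range of the noise alone over a 30-frame cycle
is ~8 px, i.e. ~0.2 cm on top of a 0.8 cm toe lift. The package reports
the range as defined rather than a bias-corrected surrogate; comparisons
between groups recorded under the same noise are unaffected, absolute
amplitudes at high noise are not.

Protraction and retraction phases are contiguous runs of positive and
negative frame-to-frame displacement. A dead-band of 0.25 px/frame
(≈ 0.4 cm/s) assigns near-zero displacements to neither phase: at stance
the displacement sign is pure noise, and without a dead-band every stance
would fragment into micro-phases. Each phase's excursion is the x
distance from its start; per cycle the maximum excursion of each type is
taken and averaged over cycles.

Joint angles use the two-argument arctangent difference at vertex P1,
normalized to [0°, 360°) (adding 360° to negative differences) — the raw
difference lives in (−360°, 360°), and per-step max/mean/min summaries
need a single branch. The four canonical neighbouring-joint triples
(hip–ankle–toe, iliac crest–hip–back ankle, elbow–wrist–front toe,
shoulder–elbow–wrist) take the middle joint as vertex. Bottom-view
paw-to-body angles measure the signed angle between the body axis (back
centre → front centre) and the midpoint→paw vector, positive to the
animal's left; the per-step amplitude is max − min within a cycle. The
"body centre" vertex is the midpoint of the two tracked centre labels —
the least-assumption reading of a centre that is not itself tracked.

## Ladder-rung misstep scoring

A misstep is a toe-tip excursion reaching at least 0.5 cm below the rung
line. The rung line comes from the config when known, otherwise from an
upper quantile (default 0.75) of the toe's stance-frame y values: toes
rest *on* rungs during stance, so their y concentrates at the rung line,
and a central-upper quantile is robust to the rare, deeper misstep
frames. Contiguous below-threshold runs form events; events separated by
fewer than 5 frames merge, and events shorter than 2 frames are dropped
as jitter (the depth rule alone would let a single bad frame create an
event). Merging implies the event *count* is not monotone as a trace
deepens — two shallow events can fuse — but event coverage is. The error
rate is `errors / total steps × 100`, with the step denominator taken
from the same run's segmentation, per paw and pooled across paws.
`compare_to_annotations()` pairs machine scores with per-rater human
annotation tables, reporting per-video rates, the Pearson correlation
matrix across raters, and event-level recall.

## The synthetic gait generator

`simulate_run()` builds all three views with fully known truth. Defaults
describe a healthy mouse at a steady walk: 0.5 s cycles, duty cycle 0.65,
6 cm strides (12 cm/s progression), diagonal pairs locked half a cycle
apart. Bottom-view paws advance one stride per cycle with motion confined
to swing; side-view joints ride the body with per-joint vertical lift
amplitudes (0.2–0.9 cm, toes largest), scaled per side by deficit
factors; side-view toes overshoot by 5% of the stride at the end of swing
and retract, giving a known protraction/retraction signature. Missteps
are scheduled dips below the rung line with a sin² profile (depth exact
at the scheduled frame; schedule them during the paw's stance, as a real
slip happens when the paw should plant). Gaussian pixel noise and
likelihood dropouts (valid frames Beta-shaped above 0.95, dropouts
uniform below 0.5, so the 0.95 cutoff is decisive) are applied last;
every random stream derives from one master seed.

The swing displacement profile is a speed trapezoid with raised-cosine
ramps over 15% of the swing at each end. A full-swing cosine profile
spends ~25% of the swing below the 10 cm/s threshold and would bias the
recovered duty cycle by ~0.09; with the trapezoid the threshold crossing
sits ~0.5 frames from the kinematic phase boundary and recovered duty
cycles land within 0.02 of nominal.

What the generator does *not* emulate: body sway and lateral paw
placement dynamics, inter-stride variability (every cycle is identical up
to noise), correlated tracker errors (identity swaps, occlusions lasting
many frames), speed changes within a run, and rearing/stopping. Passing
recovery tests therefore demonstrates that the measurement chain is
correct on clean, stationary gait — not that it is robust to every
failure mode of real tracking.

`simulate_cohort()` derives independent per-animal seeds from a master
seed and emits a run manifest; cohort sizes of 8–10 animals per group at
3–4 s per run keep the validation suite and the acceptance script fast
while leaving enough rows for a 75/25 split.

## Profiling

Per-run parameter rows (about 147 columns over both sides) aggregate by
mean per animal × timepoint; missing views leave flagged `NA` columns,
never imputed values. `rf_profile()` fits a 100-tree random forest with
unrestricted depth on a 75/25 split that is stratified by label and
performed at the *animal* level — repeated measures of one animal never
straddle the split, which would leak identity and inflate accuracy. Gini
importances are normalized to sum to 1; accuracy comes from the held-out
confusion matrix; everything is deterministic given the seed.
`top_feature_overlap()` compares top-k importance sets between
comparisons (e.g. acute vs chronic subgroup profiles, via
`filter_labels()`), and `pca_top()` projects the rows onto the leading
components of the standardized top-5 parameters, refusing constant
columns by name and dropping (with a count) rows with missing selected
features.

A small-sample caveat established by the test suite: with few training
rows and many uninformative features, individual trees can reach purity
on noise alone and never consult an informative feature, so held-out
votes dilute — perfect accuracy from a single 10-SD feature is only
guaranteed once the row count is a few times the feature count. Injury
phenotypes shift many parameters at once, which is why the simulated
cohort classifies perfectly while a lone-feature table with 30 noise
columns need not.

## Auxiliary calculators

Lesion volume sums conical frustums `h/3 (A1 + A2 + √(A1 A2))` over
adjacent serial-section pairs (areas as bases, spacing as height); with
100 slices of an analytic ellipsoid the sum lands within 0.05% of
`4/3 πabc`. The single-pellet end score is `total score / attempts × 100`
with per-attempt scores in {0, 0.5, 1}; the cylinder test yields paw
preference, symmetry and dragging ratios; the Bederson scale (0–5) is a
validated ordinal type with no arithmetic defined on it.

## Problem sizes and tolerances used in validation

The suite validates on 4 s runs (240 frames, 6–8 cycles per paw), 2×8
animal cohorts at 3 s per run, 1000-instance oracle sweeps at 1e-9, and
recovery bands of 1 frame (cycle duration), 2% (stride, vertical
movement), 0.05 (duty cycle) and 0.02 (asynchrony) on noise-free runs,
doubled under 2 px noise — except the vertical-movement range, whose
extreme-value noise bias (above) exceeds any few-percent band by
construction.
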
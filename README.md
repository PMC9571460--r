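# gaitprofiler

Markerless gait profiling for rodent locomotor recovery studies.

Modern pose-estimation trackers (DeepLabCut and friends) turn behavioral
videos into per-frame keypoint tables, but the tables themselves are not
results: a stroke researcher wants stride lengths, stance/swing timing,
limb coordination, footfall errors on a ladder, and a classifier that says
whether an animal walks like an injured one. `gaitprofiler` implements that
post-processing chain for the three-view (left, right, bottom) runway and
ladder-rung set-up used in rodent stroke work:

* **Keypoint IO and QC** — reads/writes the DeepLabCut CSV dialect (three
  header rows: scorer / bodyparts / coords), applies the pixel calibration
  (1 cm = 37.79528 px, 60 frames = 1 s) and excludes — never interpolates —
  keypoints below the 95% detection-likelihood threshold. Tracking quality
  against human labels is scored as per-bodypart pixel RMSE and the
  fraction of labels within a 17 px (≈ 0.45 cm) confidence distance.
* **Step segmentation (bottom view)** — per-paw speed
  `v_t = |x_t − x_{t−1}| · fps / px_per_cm`; frames with smoothed speed
  above 10 cm/s are *swing*, the rest *stance*; a step cycle runs from one
  stance onset to the next. From the cycles: cycle/stance/swing durations,
  duty cycle, stride length, and the diagonal-limb asynchrony ratio
  `1 − totalSync / (totalSync + totalNotSync)` (0 = perfectly coordinated),
  plus signed paw-to-body-centre angles.
* **Side-view kinematics** — per step and joint: average height and total
  vertical movement (max − min of the height above the floor reference),
  net and total horizontal excursion, maximum protraction/retraction (sign
  of the frame-to-frame displacement), and three-point joint angles
  `atan2(P3 − P1) − atan2(P2 − P1)` summarized as per-step max/mean/min for
  the four neighbouring-joint triples.
* **Ladder-rung scoring** — a misstep is a toe-tip excursion ≥ 0.5 cm below
  the rung line; the error rate is `errors / total steps × 100`, per paw
  and pooled, with tools to compare machine scoring against blinded human
  annotations.
* **Locomotor profiling** — the >100 per-run parameters are aggregated per
  animal × timepoint and fed to a random forest (100 trees, unrestricted
  depth, 75/25 animal-level split) with Gini-impurity feature importance, a
  held-out confusion matrix, top-k importance overlap between comparisons,
  and a PCA of the five most important parameters.
* **Synthetic gait simulator** — emits the same three-view tables with
  fully known ground truth (stride, duty cycle, diagonal phase offsets,
  joint lift amplitudes, one-sided deficits, scheduled missteps, pixel
  noise, likelihood dropouts), so every stage of the pipeline is validated
  against injected values.
* **Small calculators** — lesion volume as summed conical frustums
  `V = h/3 (A1 + A2 + √(A1 A2))` over serial sections, single-pellet
  grasping end score, cylinder-test asymmetry ratios, Bederson scale
  validation.

## Worked example

Simulate a run with a 30% left-side lift deficit, segment the left front
paw and extract its step parameters:

```r
library(gaitprofiler)
cal <- gait_calibration()            # 37.79528 px/cm, 60 fps
sim <- simulate_run(gait_params(deficit = list(left = 0.7, right = 1), seed = 7))

bottom <- normalize_direction(filter_likelihood(sim$views$bottom))
speed  <- paw_speed(bottom$series$front_toe_l, cal)
steps  <- segment_steps(classify_phases(speed, paw = "front_toe_l"))
steps
#> <step_cycles: 6 cycles>
#>           paw start_frame end_frame stance_start stance_end swing_start swing_end
#> 1 front_toe_l          32        62           32         52          52        62
#> ...

cycle_durations(steps, cal)
#> $cycle 0.5   $stance 0.333   $swing 0.167   $duty_cycle 0.667   $n_cycles 6

stride_length(bottom$series$front_toe_l, steps, cal)
#> [1] 6
```

Each cycle lasts 0.5 s (30 frames at 60 fps) with a 0.67 stance fraction,
and the paw covers 6 cm per stride — the values the simulator injected.
The deficit shows up in the side view as a reduced toe lift:

```r
left <- normalize_direction(filter_likelihood(sim$views$left))
vertical_stats(left$series$front_toe, steps, cal, ground_reference(left))
#> $avg_height 0.095   $total_vertical 0.557
```

0.557 cm against the intact default of 0.8 cm — the injected 30%
reduction. Downstream, `cohort_feature_table()` +
`rf_profile()`/`pca_top()` classify such animals against baselines, and
`run_extract()`/`run_report()` drive the same chain over a directory of
CSV tables (`<animal>_<timepoint>_<run>_<view>.csv`). A thin command-line
front end lives in `inst/cli/gaitprofile.R`
(`simulate | extract | profile | scores`).

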
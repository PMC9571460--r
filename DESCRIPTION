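Package: gaitprofiler
Title: Markerless Gait Profiling for Rodent Locomotor Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for markerless keypoint tracking of
    rodent locomotion. Reads DeepLabCut-style multi-header CSV coordinate
    tables from runway and ladder-rung recordings (left, right and bottom
    views), applies likelihood filtering and pixel calibration, segments
    steps into stance and swing phases from paw speed, and computes the
    full set of bottom-view (step timing, stride length, diagonal-limb
    synchronization, paw-to-body-centre angles) and side-view (joint
    heights, horizontal excursions, protraction/retraction, three-point
    joint angles) gait parameters. Detects ladder-rung missteps from
    toe-tip depth below the rung line and scores per-paw error rates.
    Profiles locomotor recovery with random-forest classification
    (Gini importance, confusion-matrix validation) and principal-component
    analysis of the most informative parameters. Includes a synthetic
    gait simulator that emits the same table dialect with fully known
    ground truth for validation, and small calculators for lesion volume
    (summed frustums) and conventional behavioural scores.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
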
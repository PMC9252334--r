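Package: gaitpose
Title: Video-Based Gait Features from Pose Keypoints with
    Concurrent-Validity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts spatiotemporal gait parameters (cadence, step count,
    hip-width-normalized step width and its variability, step-time
    variability, and, with depth data, gait speed and step length) from
    per-frame body-joint keypoint trajectories such as those produced by
    2D/3D pose-estimation libraries.  Heel-strike events are detected by
    spatiotemporal density-based clustering (ST-DBSCAN) of ankle
    trajectories, after confidence gating, gap interpolation and zero-phase
    Butterworth smoothing.  Includes the statistical battery used for
    concurrent-validity studies against an instrumented-walkway reference
    (D'Agostino-Pearson normality screen, right-tailed Spearman rank
    correlation with Bonferroni adjustment, Wilcoxon signed-rank paired
    comparisons, step-count cutoff sweeps and difference metrics), and a
    seeded synthetic 3D-walker simulator with pinhole-camera projection
    that provides ground-truth footfalls and features for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    ggplot2,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
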
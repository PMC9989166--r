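Package: ethoscore
Title: Pose-Free Machine Scoring of Rodent Aggression and Social Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of rodent behavioral assays from video and
    trajectory data. Scores resident-intruder aggression without pose
    estimation: grayscale frames are rebuilt as temporal-difference channels,
    a small convolutional binary classifier emits per-frame attack
    probabilities, and moving-average/threshold event bounding converts them
    into attack bouts and cumulative attack duration. Also computes
    three-chamber sociability readouts (cylinder proximity time from the nose
    point, locomotion path length) from tracked trajectories, and provides the
    accompanying statistics layer: zero-safe log transform, Welch two-sample
    t-tests (raw or summary input), mixed two-way repeated-measures ANOVA with
    Tukey HSD and Sidak post-hocs. Ships synthetic-data generators for
    two-animal interaction videos with ground-truth bouts, biased-walk
    three-chamber trajectories, and cohort tables, so the full pipeline is
    testable without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
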
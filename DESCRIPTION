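Package: gripletrack
Title: Grip-Force Tracking Tasks, Motor-Learning Scores, and Synthetic
    Cohorts for Cognitive-Decline Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs dual-structure (random/repeat) grip-force visual
    pursuit tracking tasks as boundary-constrained truncated Fourier
    series, scores measured force traces with the adjustability-for-
    grasping (AGF) tracking error and block-wise motor learning rates,
    simulates calibrated virtual cohorts of normal-cognition and
    mild-cognitive-impairment participants on a sprung grip device
    model (quantization, clipping, tracking lag, trial-wise error
    decay), and runs the group-comparison statistics: Shapiro-Wilk
    screening, mixed repeated-measures ANOVA with Mauchly's test and
    Greenhouse-Geisser correction, and exact-small-sample Mann-Whitney
    and Wilcoxon signed-rank tests with bootstrap interval estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
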
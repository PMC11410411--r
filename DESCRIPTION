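Package: gaitdecomp
Title: Gait Decomposition Index and Spatiotemporal Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying interjoint coordination during walking with
    the gait decomposition index: the percentage of the gait cycle in which
    exactly one joint of a pair (hip-knee, hip-ankle, knee-ankle) moves while
    the other is paused below a relative angular-velocity threshold. Includes
    a seeded synthetic gait generator with ground-truth annotations (planar
    marker forward kinematics, condition-dependent range-of-motion and pause
    structure emulating foot-drop gait under different orthotic conditions),
    coordinate-based gait event detection and cycle segmentation,
    spatiotemporal parameters (gait velocity, step length and width, double
    support, foot clearance), sagittal kinematic maxima, and the
    condition-comparison statistics stage (one-way ANOVA with Tukey HSD and
    partial eta squared, Kolmogorov-Smirnov normality screening, and
    Bonferroni-adjusted paired t-tests for comfort ratings).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
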
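Package: armplan
Title: Optimal-Control Models of Gravity-Tuned Arm Movement Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for single-degree-of-freedom arm
    movements under gravity. Implements four optimal-control models of
    rest-to-rest shoulder rotations (Smooth-Effort, minimum jerk, minimum
    torque-change, and open-loop minimum variance with signal-dependent
    noise, with and without first-order muscle dynamics), a kinematic
    feature pipeline for motion-capture marker data (zero-phase Butterworth
    filtering, velocity-threshold movement detection, symmetry-ratio
    extraction), a synthetic marker-recording generator emulating
    motion-capture experiments in normal and microgravity, and fitting
    routines that recover the gravity value used by a planner from the
    directional asymmetry of its velocity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    pracma,
    quadprog,
    jsonlite,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
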
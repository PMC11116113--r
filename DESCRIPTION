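Package: socioscope
Title: Trajectory-Based Social Interaction Detection and Longitudinal
    Colony Behavior Analysis
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative ethology toolkit for two complementary social
    behavior assays. For small-arena fly groups it detects directed social
    interactions from tracker-exported trajectories using a three-condition
    geometric definition (relative bearing below an angular threshold,
    inter-individual distance within a body-length multiple, conditions
    maintained beyond a duration threshold) and fits group-level linear and
    generalized linear models to the resulting counts, durations and speeds.
    For home-cage mouse colonies it bins RFID-annotated behavioral event
    logs into hourly time series with light/dark phase labels and nest
    covariates, computes hour-matched baseline deltas for injection
    designs, and estimates penalized B-spline group time-courses with
    pointwise difference curves. Simulators for both input kinds provide
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
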
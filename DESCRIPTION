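Package: doublestep
Title: Trajectory Analysis of Online Reach Corrections in Double-Step Pointing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing rapid goal-directed pointing movements in the
    double-step (target perturbation) paradigm. Implements the envelope method
    for estimating online correction latency (first sustained excursion of the
    perturbed hand path beyond the mean +/- 1.5 SD band of non-perturbed
    trajectories, with an 80 ms visuomotor floor), the Atkeson-Hollerbach path
    linearity index L = A/B and the maximum path offset with its latency,
    zero-phase Butterworth low-pass filtering of motion-tracker recordings,
    kinematic landmarking (peak velocity, acceleration and deceleration time,
    reach latency and duration, endpoint accuracy in degrees of visual angle),
    robust error-trial screening and median-absolute-deviation outlier
    rejection, and two-stage condition summaries. A synthetic session generator
    emulates 240 Hz electromagnetic-tracker recordings of perturbed and
    unperturbed reaches with ground-truth correction onsets and contaminant
    trials for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
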
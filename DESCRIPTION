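Package: fishrhythm
Title: Image-Based Quantification of Fish Circadian Locomotor Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A low-cost analysis pipeline for circadian locomotor activity of
    fish recorded in light-dark cycle chambers. Provides two independent
    image-based locomotion backends operating on uncompressed video: a
    frame-differencing pixel-activity method and a background-subtraction
    centroid tracker with proximity linking. Trajectories are reduced to
    standard kinematic endpoints (swimming speed, distance, angular velocity,
    meandering, freezing/swimming/rapid time-movement ratios, sleep-like
    quiescence bouts), aggregated into light/dark-labelled circadian
    profiles, and compared with min-max normalization, Spearman rank
    correlation (exact permutation p for small n), Welch two-sample t tests
    and Monte Carlo Dunnett many-to-one comparisons. A fully ground-truthed
    synthetic generator simulates diurnal and nocturnal two-state swimming
    behaviour and renders it to video, so every pipeline stage can be
    validated without any recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
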
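Package: cpforage
Title: Central-Place Foraging Analysis of Seabird Biologging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for colonial seabird biologging studies of
    central-place foraging: GPS trip segmentation with a colony buffer and
    civil-twilight filtering, cubic-spline track densification, time-depth
    recorder (TDR) dive detection and georeferencing, outbound/inbound leg
    assignment relative to the distal point, behavioural state classification
    from speed and turning angle, camera-based sociality scoring, kernel
    utilization distributions of dive locations, distance-dependent
    generalized additive mixed models of dive and social probability, linear
    mixed models of dive depth and duration with AIC-based parsimony
    selection, and colony flock-observation contingency and rank tests. A
    synthetic data generator simulates correlated-random-walk foraging trips
    with a prey-depletion halo (dive probability and depth increasing with
    colony distance) plus matching TDR, camera and flock streams with ground
    truth, so every stage of the pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    mgcv,
    lme4
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    withr
Config/testthat/edition: 3
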
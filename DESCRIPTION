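Package: seascaper
Title: Activity Seascapes from Accelerometry and Acoustic Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building 'activity seascapes' for free-ranging marine
    predators that combine two data streams: overall dynamic body
    acceleration (ODBA) from animal-borne accelerometers, summarised by a
    two-state hidden Markov model with diel and tidal covariates on the
    transition probabilities, and space-time utilization distributions
    estimated from acoustic telemetry detections with a Brownian bridge
    movement model. The diel probability of the high-activity state is
    multiplied voxel-by-voxel into the space-time utilization volume to map
    where and when animals are most active. Includes central-place and
    displacement analyses for central place foragers, an allometric
    bioenergetics model for reef sharks with Q10 temperature correction and
    swim-speed scaling, cyclic harmonic regression with AR(1) errors for
    diel sensor profiles, and a synthetic-data generator that emulates
    central-place movement on a receiver array so that every stage of the
    pipeline can be exercised end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    nlme,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
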
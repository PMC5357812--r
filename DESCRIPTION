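Package: tortmove
Title: GPS Telemetry Movement Analysis for Tortoises in Semi-Arid Rangelands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for analysing bihourly GPS telemetry of
    leopard tortoises (Stigmochelys pardalis) and similar slow-moving
    terrestrial animals. Quantifies transmitter fix error from calibration
    data and corrects step lengths by deducting the matching quantile of the
    log-transformed error distribution; screens fixes with multi-rule
    artifact filters (HDOP, clock offset, z-coordinate error, impossible
    displacement, incomplete records); extracts habitat classes and
    Euclidean distances to water and resource features from gridded land
    cover; aggregates movement to bihourly and daily records joined with
    hourly weather; and fits random-intercept linear mixed models over all
    predictor subsets with AICc ranking, Akaike-weight model averaging and
    relative importance. Includes a synthetic-data generator (habitat
    mosaic, DEM, weather, correlated-random-walk tracks, corrupted fixes
    with ground-truth artifact labels) so every stage is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
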
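Package: woundwalk
Title: Drift-Diffusion Modelling of Leukocyte Dispersal from Wounds
Version: 1.0.0
Authors@R: person("Sam", "Ellis", email = "sam.ellis@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse time-lapse tracks of immune cells near a
    wound as a one-dimensional random walk in the distance-from-wound
    coordinate. Reads cell-centroid track tables, reduces them to
    per-timepoint population moments, fits pure-diffusion (linear) and
    drift-diffusion (quadratic) models to the mean and mean-squared
    distance curves by ordinary least squares, compares the nested models
    with an F-test, and validates fitted models by Monte-Carlo simulation
    against binned spatial distributions. Includes a seeded synthetic
    track generator (biased random walk with a reflecting wound boundary)
    so the whole pipeline is testable without imaging data, and a small
    command-line interface for simulate/fit/validate runs.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
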
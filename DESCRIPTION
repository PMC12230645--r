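Package: drywoodlands
Title: Reconstruction and Archetype Analysis of Tropical Dry Woodland Change
Version: 0.1.0
Authors@R:
    person("Woodland", "Dynamics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to harmonize multi-source woodland cover rasters, screen
    them with error-matrix accuracy assessment, fuse the retained maps into an
    accuracy-weighted ensemble, reconstruct multi-epoch cover change,
    cluster per-pixel cover trajectories into change archetypes with a
    self-organizing map, and relate cover and archetypes to species-range
    overlays. Ships a synthetic-world generator with known truth (cover
    surfaces with archetype-structured trajectories, noisy multi-resolution
    source maps with known accuracy, two-observer validation samples, and
    species ranges) so every stage of the pipeline can be exercised and
    validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
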
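Package: localclo
Title: Local Clothing Insulation Prediction for Multi-Node Thermoregulation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the distribution of local (per-body-segment) clothing
    insulation from a single overall clothing insulation value using
    thresholded linear and continuous piecewise-linear regression models for
    an 11-segment body scheme. Includes the ISO 9920 data-harmonization
    equations used to unify thermal-manikin clothing datasets reported in
    different conventions (local, regional total, effective local), a Fanger
    PMV implementation with a neutral operative-temperature band solver, an
    adapter interface for multi-node thermoregulation backends with a
    deterministic stub backend, interval Jaccard similarity tools for
    comparing measured and simulated skin-temperature ranges, and synthetic
    data generators so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
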
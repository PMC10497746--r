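Package: seedhsi
Title: Single-Seed Viability Screening from Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Seed", "Phenomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for non-destructive single-seed viability screening with
    hyperspectral imaging. Covers white/dark reflectance calibration, seed
    segmentation and per-seed mean-spectrum extraction, Savitzky-Golay and
    standard normal variate spectral preprocessing, successive projections
    algorithm (SPA) key-wavelength selection, block-wise multi-scale 3D
    convolutional classification with majority-vote aggregation to whole-seed
    calls, skeleton-based sprout (bud) length measurement with pixel-to-mm
    conversion, detection and regression evaluation metrics, and a synthetic
    hyperspectral seed-scene and bud-mask generator for end-to-end testing
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
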
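Package: rodphase
Title: Grand-Canonical Monte Carlo of Hard Rods on Three-Fold Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates the adsorption and ordering of hard rectangular rods
    on a periodic two-dimensional surface with three allowed orientations
    (0, 60 and 120 degrees), using grand-canonical Monte Carlo with
    translation, deposition and evaporation moves and an optional
    per-orientation energetic bias.  Provides nematic (orientation-tensor
    eigenvalue) and smectic (normalized Fourier peak) order parameters for
    both simulated configurations and frame-indexed rod detections such as
    those produced by particle-tracking pipelines, plus seeded generators of
    ordered and disordered reference configurations, parameter-sweep
    orchestration and rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rlang,
    tibble,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
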
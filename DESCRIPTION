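Package: cbctscatter
Title: Monte Carlo Characterization and Projection-Domain Correction of
    Scatter in Dental Cone-Beam CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying and correcting scattered radiation in
    dental cone-beam computed tomography (CBCT). Provides a Monte Carlo
    photon-transport engine with per-photon scatter-order labelling for
    cylindrical phantoms with tissue-equivalent rod inserts, a fast
    analytic Beer-Lambert projector for fixtures and oracles, a
    projection-domain two-FOV scatter correction (per-pixel natural-log
    fit, extrapolation towards a narrowly collimated acquisition,
    Gaussian low-pass of the residual, subtraction), Feldkamp-Davis-Kress
    filtered backprojection with Hounsfield calibration, and evaluation
    utilities (scatter-to-primary ratio, contrast-to-noise ratio, cupping
    index, line profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
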
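Package: nanoscreen
Title: Single-Particle ICP-MS Screening of Food-Grade Titanium Dioxide
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening food-grade titanium dioxide (E 171) for
    nanoparticles by single-particle inductively coupled plasma mass
    spectrometry (spICP-MS). Simulates time-resolved intensity scans with
    known ground truth, fits ionic calibrations and estimates transport
    efficiency by the particle-size method, detects particle events above
    an iteratively estimated background, converts event intensities to
    equivalent spherical diameters and number-based size-distribution
    measurands (mean, KDE mode, D-values, percentage below 100 nm, number
    concentration), evaluates interlaboratory precision with ISO 5725-2
    and ISO 5725-5 statistics (Algorithm A/S, Cochran and Grubbs tests),
    and applies the TEM-based confirmation and nanomaterial classification
    logic built on the minimum Feret diameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
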
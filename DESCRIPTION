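Package: spicpms
Title: Single-Particle ICP-MS Time-Scan Processing for Nanoparticle
    Characterisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data reduction for single-particle inductively coupled plasma
    mass spectrometry (SP-ICP-MS/MS) time scans acquired at microsecond
    dwell times: iterative baseline estimation and 5-sigma event
    thresholding, ionic calibration and transport-efficiency calibration by
    the particle-size method, per-particle mass and spherical-equivalent
    diameter, particle number and mass concentrations per litre and per
    gram of tissue, dissolved-metal concentration, size detection limits,
    lognormal and two-component mixture size-distribution fitting, and
    classification of nanoparticle transformations (stability, dissolution,
    agglomeration) between fresh and aged suspensions. Includes a synthetic
    time-scan generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
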
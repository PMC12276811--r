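Package: tunnelvis
Title: Analysis of Free-Flight Visual Preference Assays in a Wind Tunnel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying odor-modulated spectral and intensity
    preferences of free-flying insects tracked in a laminar-flow wind tunnel.
    Provides readers for 3D trajectory tables and stimulus-run schedules;
    per-trajectory behavioral metrics (activation, recruitment to response
    volumes, and a dwell-time preference index); occupancy maps; run-level
    quality control; beta-binomial mixed models with run random intercepts
    fitted by adaptive Gauss-Hermite quadrature, with likelihood-ratio tests,
    estimated group means and Sidak-adjusted contrasts; four-parameter
    log-logistic intensity-preference curves with fixed asymptotes and
    relative-potency comparisons; photon-flux arithmetic for isoquantal LED
    calibration; and an agent-based flight simulator that generates synthetic
    runs with the statistical structure the analysis assumes.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmmTMB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
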
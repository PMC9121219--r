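Package: drawcog
Title: Drawing-Process Kinematics and Cross-Cohort Estimation of Global Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the drawing process as a digital biomarker of
    global cognition in older adults. Simulates raw digitizer pen-event streams
    (180 Hz time series of position, pressure, inclination and hover distance)
    for trail-making-style sessions in two demographically distinct cohorts,
    with kinematics linked to a latent cognition score. Extracts six drawing
    features (mean speed, speed coefficient of variation, pressure median
    absolute deviation, inclination standard deviations, pause:drawing duration
    ratio), computes covariate-adjusted partial correlations between features
    and Montreal Cognitive Assessment scores with Benjamini-Hochberg
    correction, and performs cross-cohort random-forest estimation of
    cognition scores with grid-search tuning, permutation-test inference and
    exact Shapley feature attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ranger,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
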
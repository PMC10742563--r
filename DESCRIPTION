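Package: ppgchaos
Title: Chaotic and Fractal Analysis of Photoplethysmography with
    Hemodynamic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the chaotic (fractal) component of
    photoplethysmography (PPG) signals and relate it to hemodynamics.
    Includes a four-element Windkessel (WK4) simulator with stochastic
    parameter fluctuation that serves as a fully synthetic test bed, beat
    detection and quality filtering, per-beat hemodynamic estimation
    (peripheral resistance, compliances, inertance), IRASA separation of
    fractal and oscillatory spectral power, Higuchi and Katz fractal
    dimensions, sample/approximate/fuzzy entropy, recurrence
    quantification, heart-rate-variability indices, and
    correlation/sensitivity/Granger-causality association analyses over
    sliding windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
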
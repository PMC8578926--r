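Package: pulsees
Title: Left-Ventricular End-Systolic Elastance from Brachial Pressure Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico pipeline for estimating left-ventricular end-systolic
    elastance (Ees) from a single brachial blood-pressure waveform. A reduced-order
    cardiovascular simulator (time-varying elastance ventricle coupled to a tapered
    lumped-ladder arterial network with three-element Windkessel terminals) generates
    a virtual population of pressure waveforms with known Ees; subjects are screened
    with a blood-pressure plausibility filter; one- and two-channel one-dimensional
    convolutional regressors are trained on the waveform and its time derivative; and
    predictions are evaluated with Pearson correlation, range-normalized RMSE,
    Bland-Altman agreement and a white-noise robustness sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
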
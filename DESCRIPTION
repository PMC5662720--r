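Package: toatrack
Title: Time-of-Arrival State-Space Positioning for Acoustic Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates tracks of acoustic-tagged aquatic animals directly from
    time-of-arrival (TOA) data recorded on a synchronized hydrophone array.
    Implements the YAPS approach: a state-space model coupling random walks for
    position, transmission time and speed of sound with a robust Gaussian plus
    scaled t (3 df) mixture for TOA residuals, fitted by maximum likelihood
    with the latent states integrated out by the Laplace approximation.
    Also provides a classical hyperbolic (TDOA) multilateration baseline, a
    forward simulator of tracks and degraded TOA matrices (missed detections,
    multipath offsets), and track-accuracy metrics for comparing estimators.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tidyr,
    TMB,
    utils,
    yaml
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    numDeriv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
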
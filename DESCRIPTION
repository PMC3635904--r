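Package: speedsig
Title: Stochastic Signatures of Trial-to-Trial Hand-Speed Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the micro-variability of peak hand speed across
    repeated movement trials as a stochastic process. Provides a seeded
    generator of synthetic motion-capture sessions (bell-shaped speed
    profiles, curved retraction trajectories, log-normally fluctuating peak
    speeds, blocked or randomly interleaved speed designs), per-trial
    kinematic feature extraction with Savitzky-Golay smoothing, Gamma-plane
    stochastic signatures fitted by maximum likelihood with noise-to-signal
    (Fano) ratios, a first-order log-log stochastic rule linking consecutive
    trials, Hartigan's dip test of unimodality with bootstrap calibration,
    trajectory-linearity profiles, nonparametric condition comparisons,
    fatigue checks, and expertise criteria combining bandwidth and
    noise-to-signal thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    graphics,
    grid,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
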
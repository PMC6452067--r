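Package: sonarcee
Title: Multi-Scale Controlled Sonar Exposure Experiment Analysis for
    Cetacean Biologging, Telemetry and Passive Acoustic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for behavioural response studies in which
    tagged cetaceans are experimentally exposed to naval-sonar signals.
    Provides seeded synthetic-data generators for high-resolution tag
    records, satellite tracks, passive acoustic scenes and sonar
    transmission schedules; extraction of movement and locomotion
    variables from tag sensor data; Mahalanobis-distance change-point
    detection with a calibrated resampling threshold; a gamma-likelihood
    dose-response-intensity model compared across a reduced-model family
    by AIC; hidden Markov models of hourly step lengths and turn angles
    with exposure-recovery covariates on transition probabilities; a
    guard-band energy detector for echolocation clicks with a
    click-absence outlier statistic; and Monte-Carlo propagation of
    positional and depth uncertainty into received sound pressure levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
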
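Package: rhythmscreen
Title: Circadian Phenotyping of Home-Cage Activity Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for circadian phenotyping screens based on
    minute-binned home-cage locomotor activity (capacitive-sensor animal
    locomotion index). Implements the chi-square periodogram with a
    per-period chi-square significance line, the nonparametric
    rest-activity disruption metrics (inter-daily stability, intra-daily
    variability, relative amplitude via M10/L5), activity-bout length
    distributions, light-phase activity fractions, step-template activity
    onset detection, light-pulse phase-shift estimation (Aschoff type II)
    and jet-lag re-entrainment timing, together with a seeded synthetic
    cohort simulator that reproduces a multi-week lighting protocol
    (entrained light-dark, constant darkness, constant light, a 6-h phase
    advance and a phase-delaying light pulse) so every stage of the
    pipeline can be validated against known ground truth.
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
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
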
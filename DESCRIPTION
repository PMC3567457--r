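Package: segerp
Title: Infant ERP Speech-Segmentation Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for infant event-related potential (ERP)
    studies of speech segmentation: artifact-screened epoching of
    multi-channel EEG, condition averaging and difference waves,
    window-mean amplitude tables over electrode quadrants,
    repeated-measures ANOVA with Greenhouse-Geisser and Huynh-Feldt
    sphericity corrections, sliding-bin onset-latency detection,
    polarity-based responder classification, and linkage of the
    left-frontal familiarity effect to language outcomes at age three.
    Includes a seeded synthetic-cohort generator that emulates the
    statistical structure of a two-phase familiarization/test
    segmentation experiment (planted familiarity effects for two
    responder subpopulations, pink-noise EEG, ocular and excursion
    artifacts, and linked outcome scores) so that every stage of the
    pipeline can be validated by parameter recovery without access to
    infant EEG recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
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
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
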
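Package: pavlovo2
Title: Rescorla-Wagner Modelling and Prediction-Error Analysis of
    Pavlovian Tissue-Oxygen Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing probabilistic Pavlovian conditioning
    experiments in which haemodynamic (tissue-oxygen amperometry) signals
    are recorded alongside magazine-approach behaviour. Provides a
    synthetic-data generator for the two-cue 75/25 task (schedules,
    Rescorla-Wagner agents, HRF-convolved oxygen traces), a grid of
    modified Rescorla-Wagner learning models fitted by maximum likelihood
    and compared by BIC, event-locked epoching with area-under-the-curve
    summaries, trial-by-trial regression of neural responses on
    model-derived value and prediction-error latents (signed and
    unsigned), and permutation-based pre/drug contrasts emulating an
    acute amphetamine challenge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
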
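Package: ergochoice
Title: Ergodicity-Aware Stated-Choice Lottery Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing stated-preference
    lottery experiments that probe whether decision makers optimise
    time-average growth or ensemble-average (expected) value. Provides
    additive and multiplicative wealth-dynamics simulators with ergodicity
    diagnostics, a seeded generator of equal-expected-value unequal-variance
    bet couples (plus dominated "no-brainer" attention checks), a synthetic
    respondent simulator with configurable decision models and response-time
    distributions, a no-brainer quality-control filter, and a two-stage
    Jeffreys-prior beta-binomial estimation pipeline with setting-level
    aggregation, one-sided z-tests, Mann-Whitney response-time comparisons
    and a standardized final-capital ranking.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
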
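Package: stopsig
Title: Hierarchical Bayesian Stop-Signal Modelling and MRS Metabolite
    Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying response inhibition and its neurochemical
    correlates. Implements a stop-signal task engine with staircase tracking
    of the stop-signal delay, an ex-Gaussian race model with go-failure and
    trigger-failure mixtures, hierarchical Bayesian estimation of the race
    parameters by differential-evolution MCMC with migration, posterior
    distributions of the stop-signal reaction time (SSRT), CRLB-weighted
    covariate correction of MR spectroscopy metabolite concentrations, and a
    Bayesian Spearman-correlation decision procedure based on highest density
    intervals and a region of practical equivalence. A synthetic cohort
    generator reproduces the statistical structure of a two-group
    patient/control study so that the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    emmeans,
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
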
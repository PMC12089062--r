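Package: roadcline
Title: Road-Mortality Selection on Color Morph Clines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether road mortality acts as a selective
    force on a discrete color polymorphism along an urban-rural gradient.
    Implements a hierarchical N-mixture model that integrates point counts
    and camera-trap detection histories to estimate the living cline in
    morph frequency, a Bernoulli cline model for road-killed (DOR)
    individuals, posterior contrasts of the two clines, Firth
    mean-bias-reduced logistic regressions of morph-specific mortality risk
    with backdoor adjustment sets identified from a causal DAG, and
    contingency statistics for citizen-science photo classifications. A
    synthetic-data generator with known truth makes the whole workflow
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
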
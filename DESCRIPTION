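Package: cagedemog
Title: Demographic Analysis of Lifespan and Fecundity from Cage Censuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for demographic analysis of thrice-weekly cage censuses from
    factorial diet experiments on insect cohorts. Provides a synthetic
    cage-census generator (Gompertz mortality, piecewise-constant fecundity,
    Monday/Wednesday/Friday observation with censoring), product-limit survival
    curves with percentile lifespans and log-rank comparisons under
    Benjamini-Hochberg correction, per-female fecundity summaries with Hedges' d
    effect sizes, penalised mean-shift changepoint segmentation of egg-laying
    series (PELT, exhaustive dynamic programming, binary segmentation), and
    life-table construction feeding Leslie-matrix eigen analysis: the asymptotic
    growth rate lambda, stable age distribution, reproductive values Vx, and
    damping ratio rho.
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
    survival,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
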
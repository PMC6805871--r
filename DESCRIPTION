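Package: stochcal
Title: Genetic-Algorithm Calibration of Stochastic Kinetic Models with
    Equivalence-Test Fitness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates the rate parameters of stochastically simulated kinetic
    models against replicated experimental time series using a genetic
    algorithm. Provides nine algebraic fitness functions (SDA, ADA, PWSD,
    APWSD, NPWSD, ANPWSD, SSQ, CHISQ, MNSE), three iterative equivalence tests
    used as discrete fitness functions (two one-sided t-tests, the double
    Mann-Whitney U-test, and Wellek's nonparametric equivalence test), three
    selection/recombination/mutation strategies with optional elitism,
    multi-objective ranking by unweighted rank sums, a built-in exact Gillespie
    stochastic simulator for mass-action reaction networks, model templating
    for external command-line simulators, parallel simulation dispatch, and
    jackknife/bootstrap parameter-uncertainty estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
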
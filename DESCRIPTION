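Package: mostscreen
Title: Design, Simulation and Analysis of 2^k Factorial Screening Experiments
    for Digital Intervention Engagement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the screening phase of the Multiphase Optimization
    Strategy (MOST) applied to digital-intervention engagement outcomes.
    Simulates balanced 2^4 factorial trials with stratified permuted-block
    randomization and correlated binary feature-use outcomes; prepares
    engagement outcomes (feature-use counts, 1:2 dichotomization of skewed
    usage metrics with sensitivity sweeps); fits full-factorial logistic and
    quasi-Poisson models; estimates marginal factor effects with standardized
    mean differences and parametric percentile bootstrap confidence
    intervals; summarizes all 16 arms with reduced-level confidence intervals
    calibrated so that interval overlap corresponds to a pairwise test, and
    ranks arms; and reproduces normal-approximation power and minimum
    detectable effect calculations with Bonferroni multiplicity adjustment.
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
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
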
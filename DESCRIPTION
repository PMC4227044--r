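Package: banditpool
Title: Simulation and Criterion-Model Analysis of a Rule-In/Rule-Out
    Commitment Bandit Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulation and behavioural modelling of a
    four-bandit economic commitment task with persistent asset-pool
    payoffs. Blocks present noisy spiral-length evidence for four bandits
    whose payoffs are rank-relative within a context; under the rule-in
    frame commitments accept bandits into an asset pool, under rule-out
    they reject bandits from an initially full pool, and deferral
    postpones the irreversible decision. The package computes the family
    of anchored/integrated decision variables (current-minus-average,
    current-minus-next, and relatives), fits probit and deterministic
    criterion choice models by maximum likelihood with BIC comparison,
    locates reward-maximizing commitment criteria by Monte-Carlo grid
    search, summarizes commitment behaviour (commit probabilities by
    rank, context and trial; commitment counts; first-commitment
    trials), derives trialwise model regressors, and generates synthetic
    cohorts with known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
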
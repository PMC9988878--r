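Package: moralbandit
Title: Reinforcement Learning of Action Outcomes Under Moral Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, hierarchical Bayesian fitting, and comparison of
    Rescorla-Wagner reinforcement-learning models for a two-armed bandit in
    which one option yields high monetary gain for the decider but a painful
    shock to another person (moral conflict). Implements a model family that
    differs in where an individual weighting factor between self-money and
    other-shock enters (outcome phase, decision phase, or distributed), the
    devaluation (outcome-dropout) predictions that arbitrate between them,
    PSIS-LOO and held-out-trial model comparison, binomial preference
    classification, explicit-report bias statistics, parameter-recovery
    simulation, and wf-normalized regressor construction for downstream GLMs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
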
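Package: rlddm
Title: Reinforcement-Learning Diffusion Decision Modelling of Valence and
    Feedback Effects in Instrumental Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for jointly modelling choices and response times in
    probabilistic instrumental learning tasks that cross outcome valence
    (reward vs punishment) with feedback information (partial vs complete).
    Implements the Wiener first-passage-time likelihood of the diffusion
    decision model (DDM), context-dependent Q-learning with a learned
    context value used as the reference point for prediction errors, and
    trial-wise linking of the learned value difference, decision conflict
    and context value to the drift rate, threshold and non-decision time.
    Provides a task simulator for cohorts of learning agents, hierarchical
    Bayesian estimation by adaptive Metropolis-within-Gibbs, convergence
    diagnostics, posterior predictive checks, parameter recovery, a
    condition-coded factorial DDM, and Bayesian effect estimation for
    accuracy and response-time cell means.
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
    readr,
    rlang,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    ggplot2
Config/testthat/edition: 3
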
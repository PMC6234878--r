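Package: phyniche
Title: Substrate-Niche Evolution on Posterior Tree Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenetics toolkit for studying the evolution of a
    discrete ecological niche (e.g. preferred substrate of lichen-forming fungi)
    across a posterior sample of time-calibrated trees. Provides Mk discrete-trait
    models with arbitrary constraint masks and a pruning-likelihood core,
    maximum-likelihood fitting and AIC ranking of exhaustively enumerated
    "no-switch" (absorbing-state) transition models, marginal ancestral-state
    reconstruction and majority-vote ensembles over method x model x tree grids,
    stochastic character mapping by uniformization with transition counting,
    permutation tests of phylogenetic signal (Pagel's lambda scenarios and
    same-state cophenetic distances), multi-state speciation-extinction (MuSSE)
    likelihoods with ML and MCMC inference, and forward simulators for
    birth-death trees, Mk characters and state-dependent diversification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.6),
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
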
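Package: ecopinn
Title: Process-Informed Neural Networks for Ecosystem Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid mechanistic-statistical modelling framework combining
    process-based simulators with multi-layer perceptrons. Provides a
    differentiable predator-prey (Lotka-Volterra) simulator with type I and
    type III functional responses, a miniature light-use-efficiency carbon
    and water flux model with coupled soil-water pools, five
    process-informed neural network (PINN) architectures (bias correction,
    parallel physics, physics regularisation, domain adaptation via
    simulator pretraining, and physics embedding) alongside naive-MLP and
    process-model baselines, stand-alone calibration by adaptive Metropolis
    MCMC and by gradient descent through analytic forward sensitivities,
    blocked cross-validation and random-search training protocols,
    synthetic multi-site daily flux data generators with controlled
    structural mismatch, and post hoc individual-conditional-expectation
    variable-importance analysis over seasonal windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
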
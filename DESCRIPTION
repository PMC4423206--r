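Package: rangexp
Title: Eco-Evolutionary Dynamics of Range Expansions with Explicit
    Consumer-Resource Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how dispersal and foraging traits evolve
    during range expansions of consumers feeding on dynamic resources.
    Provides deterministic growth models (logistic and Rosenzweig-MacArthur
    consumer-resource dynamics with a type II functional response),
    nonlinear least-squares fitting of growth curves with AIC-based model
    comparison and resource-dependent fitness estimation, a stochastic
    individual-based simulator of range expansion under a
    dispersal-foraging trade-off with an evolving trait simplex, summary
    statistics for movement trajectories (velocity, circular standard
    deviation of turning angles), and seeded synthetic-data generators for
    growth curves and correlated random walks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
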
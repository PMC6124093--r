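Package: colonyabc
Title: Approximate Bayesian Computation for Lattice Models of Growing
    Cell Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and likelihood-free inference for a
    two-dimensional lattice exclusion-process model of cell motility and
    proliferation, as used to analyse growth-to-confluence and scratch
    (wound-healing) assays. Provides the stochastic simulator, thirteen
    spatial and trajectory summary statistics, ABC rejection with
    median-absolute-deviation weighted distances, local-linear regression
    adjustment and Gaussian kernel density posteriors, data-cloning
    ABC-MCMC for maximum-likelihood estimation, Kullback-Leibler
    information gain for comparing experimental designs and
    summary-statistic choices, and posterior predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
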
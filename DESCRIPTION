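Package: inhibcircuit
Title: Effective Connectivity Analysis of the Basal Ganglia-Thalamocortical
    Response Inhibition Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and Bayesian inversion of a four-node bilinear
    dynamic causal model (inferior frontal gyrus, caudate, globus pallidus,
    thalamus) of response inhibition during Go/NoGo performance. Provides a
    balloon-model BOLD generator, a Go/NoGo paradigm and multi-subject cohort
    simulator with configurable sex and performance effects, event-related GLM
    utilities with region-of-interest extraction, single-subject variational
    Laplace model inversion, and group-level parametric empirical Bayes with
    Bayesian model reduction, model averaging, Bayesian contrasts and
    behavioral statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix
Config/testthat/edition: 3
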
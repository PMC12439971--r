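Package: fptdecouple
Title: Decoupling of Steady-State Level and Activation Time in
    Ligand-Regulated Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing input-output responses of ligand-regulated
    molecular systems modelled as continuous-time Markov processes on
    labelled directed graphs (the linear framework). Provides exact
    steady-state probabilities and mean first-passage times by three
    independent routes (dense linear algebra, the Chebotarev-Agaev
    spanning-forest recurrence in numeric and symbolic form, and
    brute-force spanning-forest enumeration), normalised concentration
    response curves and their dynamic ranges, a coupling score that
    quantifies decoupling between the steady-state readout level and the
    activation time, closed-form expressions for small chain and ladder
    models, Gillespie simulation of first-passage times, and constrained
    particle swarm optimization campaigns that locate decoupling regimes
    such as rate scale separation and incoherent regulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
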
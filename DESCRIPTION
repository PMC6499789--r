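Package: medcoex
Title: Mediator-Explicit Simulation of Microbial Community Coexistence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates communities of microbes that interact through chemical
    mediators (metabolites, toxins, signals) which they produce and consume.
    Couples species densities to mediator concentrations with pluggable
    facilitation (Monod/Moser) and inhibition (linear/threshold/saturating)
    response laws, runs serial grow-dilute enrichment with extinction and an
    operational coexistence definition, samples random bipartite interaction
    networks, and provides ensemble screens (richness distributions, mean
    excess richness with bootstrap intervals, influence-category enrichment,
    in-silico knock-outs, depletable-versus-reusable mediator comparisons), a
    chemostat steady-state eigenvalue analysis, and utilities to extract
    growth rates from plate-reader optical-density series and fit
    dose-response laws.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
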
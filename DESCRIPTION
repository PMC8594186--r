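Package: retrosse
Title: State-Dependent Diversification Analysis of LINE-1 Retrotransposition
    Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the population dynamics of LINE-1 (L1)
    retrotransposons from phylogenies of genomic L1 insertions with binary
    retrotransposition-activity states. Implements the binary-state
    speciation and extinction (BiSSE) likelihood with an epoch/change-point
    extension in which both speciation rates are rescaled by a shared factor
    in older epochs, constrained maximum-likelihood fitting with AIC model
    comparison pooled over a sample of trees, a two-state Markov (Mk2)
    likelihood with reversible-jump MCMC over transition-rate constraints,
    the asymptotic L1 growth-rate calculation (dominant eigenvalue of the
    2x2 low/high-activity dynamics matrix, equilibrium activity mix and
    doubling times), and a Gillespie-style forward simulator of trees and
    tip activities under known parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
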
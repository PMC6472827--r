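Package: phylomc
Title: Bayesian Phylodynamic Inference on Time Trees with Sampled Ancestors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A compact Bayesian phylodynamic inference engine for rooted time
    trees. Provides Metropolis-Hastings MCMC over tree space including
    sampled-ancestor (degree-2) nodes, birth-death tree priors with serial
    sampling and piecewise-constant (skyline) rates in both canonical and
    epidemiological parameterizations, the serial coalescent, reversible
    nucleotide substitution models indexed by six-digit rate-grouping codes
    with reversible-jump model averaging, Felsenstein pruning likelihoods with
    gamma rate heterogeneity and an invariable-sites fast path, marginal
    likelihood estimation by nested sampling, path sampling and stepping-stone,
    and direct simulators of trees and sequences for well-calibrated validation
    and posterior-predictive model adequacy checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
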
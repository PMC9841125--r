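Package: zipfec
Title: Hierarchical Zero-Inflated Poisson Models of Avian Fecundity
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a hierarchical Bayesian zero-inflated Poisson model of
    annual fecundity (juveniles produced per breeding pair) with a Bernoulli
    brood-success submodel and a Poisson count submodel, year random effects
    on both submodels, and population and territory random effects on counts.
    Includes an adaptive Metropolis-within-Gibbs sampler with a
    run-until-converged protocol, posterior predictive checking via the
    Freeman-Tukey discrepancy, a Bayesian runs test for serial patterns in
    annual random effects, the cross-submodel correlation of year effects,
    covariate-profile prediction, and a synthetic territory-year panel
    generator that reproduces the unbalanced multi-population panel structure
    of long-term cooperative-breeder monitoring studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
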
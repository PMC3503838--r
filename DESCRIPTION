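Package: gmycbayes
Title: Bayesian and Likelihood Species Delimitation with the General
    Mixed Yule-Coalescent Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-locus species delimitation on ultrametric gene trees
    with the general mixed Yule-coalescent (GMYC) model. Branching events
    are classified as speciation (Yule process) or within-species
    coalescence by a time threshold; the package estimates the threshold
    by a maximum-likelihood scan with likelihood-ratio test and Akaike
    weights, and by Metropolis-Hastings MCMC yielding marginal posterior
    distributions of the number of species and of pairwise
    co-conspecificity, optionally pooled over a posterior sample of trees
    to integrate over phylogenetic uncertainty. Includes a simulation
    framework (Yule species trees, multispecies-coalescent gene trees,
    allele-sampling schemes, HKY+G sequence simulation, and a
    structured-coalescent island model) for validating the method, and an
    alignment deduplication utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
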
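Package: riskevo
Title: Evolution of Extinction Risk on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of IUCN extinction-risk categories, coded as
    integer states, across a species phylogeny. Provides disparity-through-time
    (DTT) curves with simulation and permutation nulls for assessing
    phylogenetic conservatism of risk, and maximum-likelihood fitting of four
    time-dependent equal-rates Markov models of discrete trait evolution
    (constant rate, Pagel delta, linearly changing rate, and a two-rate
    breakpoint model) compared by AIC. Includes majority-rule consensus with
    averaged branch lengths, penalized-likelihood ultrametricization, seeded
    simulators for pure-birth trees and discrete/continuous traits, and an
    end-to-end pipeline from a species-by-category table to the model
    comparison table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phytools,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
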
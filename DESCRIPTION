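Package: swidden
Title: Coupled Social-Ecological Dynamics of Swidden Agriculture
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of swidden ('slash-and-burn')
    agriculture in a community forest. Households on a lattice forest
    ecosystem request field clearings and exchange labour; helping
    decisions combine direct reciprocity with normative reasoning
    (withholding help from unacceptably large requests acts as a
    sanction). Clearing requests are revised by myopic best response
    under expected-helper beliefs and sanctioning thresholds evolve by
    logit payoff-based imitation with random innovation. The package
    provides the full round engine (compiled and pure-R reference
    implementations), ensemble and parameter-sweep machinery, regime
    classification, a mean-field forest equilibrium, a graduated
    sanctioning index, and configuration/CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
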
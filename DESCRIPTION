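Package: lepihost
Title: Butterfly-Host Plant Association Matrices, Diversity, Congruence and
    Ancestral Host Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of butterfly-host plant associations at the
    subfamily by plant-order level. Builds binary, count, proportion and
    important-link association matrices from host-use records; measures host
    diversity per butterfly subfamily (order richness, Fisher's log-series
    alpha, Faith's phylogenetic diversity with a random-sample null);
    correlates host diversity with butterfly species richness through
    phylogenetically independent contrasts; tests cophylogenetic congruence
    between plant and butterfly phylogenies with ParaFit permutation tests;
    and estimates ancestral host states on butterfly cladograms under
    constrained Mk models with one-directional transitions to derived states,
    compared by AIC. A synthetic-data generator produces every input the
    pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    phytools,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
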
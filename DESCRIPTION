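Package: agreeforest
Title: Maximum Agreement Forests and rSPR Distance for Rooted Binary Trees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the Maximum Agreement Forest (MAF) problem on two
    rooted binary phylogenetic trees, which computes the rooted
    subtree-prune-and-regraft (rSPR) distance. Provides a combinatorial
    2-approximation (the Red-Blue algorithm) that certifies its own
    solution quality through a dual-fitting lower bound, an exact
    brute-force solver for small instances, linear-programming
    relaxations (an enumerated set-partition formulation and an
    equivalent compact arborescence formulation) with integrality-gap
    computation, and generators for random and SPR-perturbed instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
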
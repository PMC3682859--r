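Package: mpclad
Title: Maximum-Parsimony Cladistics for Binary Morphological Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact maximum-parsimony analysis of binary morphological
    character matrices: NEXUS matrix input and output with faithful handling
    of missing, inapplicable and polymorphic cells, Fitch tree-length
    scoring, exact branch-and-bound search for all most-parsimonious trees,
    heuristic search with random stepwise addition and tree
    bisection-reconnection swapping, strict and majority-rule consensus
    trees, jackknife support by random character deletion, ACCTRAN
    ancestral-state reconstruction with per-branch apomorphy lists, ensemble
    fit statistics (consistency, retention and rescaled consistency
    indices), and a binary-character simulator for validation. Ships a
    published 20-taxon, 19-character matrix of chordate oral
    secondary-sensory-cell morphology as a built-in data set and reproduces
    its full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
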
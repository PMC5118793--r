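Package: llna
Title: Life-Like Network Automata for Pattern Recognition in Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves binary Life-like cellular automata on arbitrary network
    tessellations by mapping birth/survival neighbour counts onto nine
    neighbourhood-density intervals, and turns the resulting space-time
    diagrams into fixed-length descriptors (Shannon entropy, word-length and
    Lempel-Ziv complexity histograms) for network classification. Includes
    generators for random, small-world, scale-free and geographical synthetic
    networks, structural-measure baselines, rule-selection scans,
    cross-validated classification experiments, and proximity-network
    construction from two-dimensional point patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    class,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
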
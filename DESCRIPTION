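Package: netperturb
Title: Multi-Omic Interactome Assembly, Virtual Knockout and Network
    Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles multi-layer molecular catalogs into protein-protein
    interaction networks, computes degree, betweenness and stress
    centrality on the main connected component, simulates drug-target
    knockout with an empirical permutation null and Benjamini-Hochberg
    correction on per-node centrality changes, and classifies
    node-importance transitions between a directed single-omic map and an
    undirected multi-omic map by degree percent-rank. Includes a
    deterministic synthetic-data generator emulating the statistical
    structure of curated rheumatoid-arthritis interactome inputs, a
    fold-change differential-expression filter with probe collapse, and
    hypergeometric over-representation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
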
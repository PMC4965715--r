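Package: gacomplex
Title: Protein Complex Prediction in Interaction Networks with Genetic Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts (possibly overlapping) protein complexes in
    protein-protein interaction networks with a mutation-only genetic
    algorithm. Candidate clusterings are scored with a density-based
    fitness that rewards intra-cluster cohesion and penalizes
    inter-cluster coupling, or with multiway generalizations of the
    min-max, ratio, and normalized cut objectives. Populations are
    initialized at random or from a recursive spectral bisection of the
    network (Fiedler vector of the generalized Laplacian problem).
    Predicted complexes are scored against reference catalogs such as
    CYC2008 or MIPS via hypergeometric enrichment, with
    precision/recall/F-measure summaries and discard ratios. A planted
    complex simulator generates benchmark networks with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
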
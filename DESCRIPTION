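Package: fuzzysig
Title: Knowledge-Guided Fuzzy Logic Modeling of Cellular Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers context-specific cellular signaling networks from
    (phospho)proteomic perturbation data by calibrating a confidence-scored
    prior knowledge network with a fuzzy logic model. Edges of the prior
    network carry publication-derived confidence scores; candidate networks
    are executed as normalized-Hill fuzzy logic models (or Boolean networks)
    under synchronous updates; goodness of fit is measured by mean squared
    error for steady-state perturbation panels or by dynamic time warping for
    temporally-ordered time series; and structure learning is posed as a
    constrained nonlinear integer program over adjacency, gate-membership and
    sign matrices, solved by a multi-restart genetic algorithm with
    quantitative-prior and indegree regularizers. Includes network
    compression of undesignated pass-through proteins, synthetic-data
    generators for benchmarking, a random-prior significance test, and
    Boolean cell-fate prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
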
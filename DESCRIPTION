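Package: micAssembly
Title: Microbial Community Assembly from Neutral Models, Phylogenetic
    Nulls, and Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the contributions of stochastic and
    deterministic processes to microbial community assembly from amplicon
    OTU tables. Implements the Sloan neutral community model (occurrence
    frequency predicted from mean relative abundance via the beta
    distribution, with confidence-band classification of taxa into
    neutral, selected-for and selected-against), nearest-taxon-index
    (NTI) phylogenetic null models with per-plot tests, core-microbiome
    occupancy partitions and abundance-occupancy relationships,
    bacterial-fungal association network statistics with
    degree-preserving and Erdos-Renyi null models and a cross-network
    shared-association permutation test, and a neutral (Moran)
    community simulator that generates study-design-shaped synthetic
    data sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    ape,
    vegan,
    picante,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
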
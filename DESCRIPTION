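Package: metamlann
Title: Multi-Label Neural Network Inference of Urban Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts presence/absence of microbial genera at unsampled
    urban locations from transit-network, ridership and surface-material
    features. Implements the MetaMLAnn architecture: a feed-forward
    multi-label network with per-label and shared hidden blocks, trained
    with a cross-entropy objective regularized by the graph Laplacian of a
    phylogenetic (sequence-identity) genus similarity matrix. Ships an
    inverse-distance-weighting spatial baseline, a convex-combination
    ensemble (MetaMLAnn+), a micro-averaged evaluation and cross-validation
    harness, feature builders for station/line, node2vec-style transit-graph
    embedding and surface-material features, parsers for MetaPhlAn-style
    relative-abundance profiles, and a synthetic-data generator that
    emulates every input with planted, recoverable structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Biostrings,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
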
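Package: gpsample
Title: Graph Partition Sampling and Embedding for Power-Law Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sampling, partitioning and unsupervised embedding machinery for
    large sparse interaction networks with power-law degree structure, such as
    protein-protein interaction graphs. Provides biased second-order random
    walks (node2vec style), fixed-fanout neighbor sampling with truncation and
    fill, degree-ordered graph partitioning with balance diagnostics,
    hypergraph partitioning by randomized local search over replication-based
    communication costs, and the node2vec, LINE (first and second order) and
    GraphSage unsupervised objectives trained by stochastic gradient descent
    on synthetic or user-supplied edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
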
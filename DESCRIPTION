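Package: pagar
Title: Partition-Based Graph Abstraction for Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the connectivity between partitions of a single-cell
    k-nearest-neighbor graph and abstracts the graph into a coarse,
    topology-preserving map (a PAGA graph). Includes count preprocessing and
    graph construction, Louvain partitioning, the partition connectivity test
    statistic with spurious-edge thresholding and spanning-tree extraction,
    directed abstraction of RNA-velocity graphs, diffusion pseudotime extended
    to disconnected graphs, topology-preserving embedding initialization, the
    KL_geo embedding-faithfulness measure and a path-set topology comparison
    score, plus a ground-truth simulator for branching expression manifolds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
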
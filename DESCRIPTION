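Package: chamclust
Title: Graph-Based (Chameleon-Style) Clustering and Evaluation for
    Community Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-phase graph-theoretic clustering for plot-by-species
    community data in the style of the Chameleon algorithm: a sparse
    k-nearest-neighbour similarity graph is partitioned by recursive
    min-weight bisection and the resulting sub-partitions are optionally
    merged by hierarchical agglomeration.  The package also provides the
    traditional baselines the method is usually compared against (k-means
    on coordinates, k-medoids on a similarity matrix, flexible-beta group
    averaging, and polythetic division), internal evaluation metrics
    (nearest-neighbour misplacement rate, within-cluster homogeneity,
    cluster-size evenness), diagnostic-species scoring (cumulative
    hypergeometric tail and standardized phi fidelity), confusion-matrix
    comparison with an expert reference classification, and synthetic-data
    generators for uneven Gaussian point clusters and structured
    presence-absence community matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    vegan,
    withr
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
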
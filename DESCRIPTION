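Package: hierembed
Title: Hierarchical Metric-Learning Embeddings for Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns a single unit-hypersphere embedding space for protein
    sequences in which Euclidean distances reflect a three-level family
    hierarchy (family / subfamily / sub-subfamily). A multi-kernel
    convolutional feature extractor with one-max pooling feeds a linear
    embedding layer with L2 normalization and three classifier branches,
    trained with per-level softmax cross-entropy plus a per-level center
    loss under a three-phase curriculum. Includes a motif-planting
    synthetic-data generator, embedding-space evaluation (silhouette,
    adjusted mutual information versus cluster count, UPGMA ordering,
    neighbor-joining phylogeny) and exact nearest-neighbor similarity
    search over embedding databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    cluster,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
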
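Package: deepcmf
Title: Deep Collective Matrix Factorization with Knowledge-Graph Similarity Views
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Learns shared low-dimensional entity representations from
    arbitrary collections of relational matrices by collective training of
    one autoencoder per entity (deep collective matrix factorization), in
    unsupervised or supervised (task-augmented) mode. Includes a global
    resource allocation (GRA) path-based node similarity engine so that
    literature-derived knowledge-graph structure can be injected as
    additional square views, subject-predicate-object triplet filtering,
    TF-IDF concept-matrix construction from per-episode mention records, a
    synthetic multi-view data generator with known latent structure, and an
    evaluation harness (split protocol, classification metrics, stacked
    denoising autoencoder and alternating-least-squares baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    yaml,
    nnet,
    randomForest,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
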
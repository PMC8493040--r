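Package: gosimnet
Title: Protein Similarity Networks from Gene Ontology Graph Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds protein functional similarity networks from the Gene
    Ontology (GO). Parses OBO ontologies and GAF annotation files, flattens
    them into undirected GO and GO-annotation (GOA) graphs, and learns node
    vectors with random-walk (DeepWalk, node2vec) and deep (LINE, SDNE)
    graph embeddings. Protein pairs are scored either by dynamic time
    warping over the embedding vectors of their annotated terms or by
    cosine similarity of protein vectors learned from the GOA graph.
    Information-content baselines (Jiang-Conrath and relevance similarity
    with best-match averaging) are included, together with a
    link-prediction protocol (common-neighbours, Jaccard and
    resource-allocation indexes; AUC and precision-recall curves) for
    evaluating screened similarity networks, and generators for synthetic
    ontologies, annotation sets and protein interaction networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
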
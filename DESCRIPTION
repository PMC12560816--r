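Package: kgtopo
Title: Topology-Aware Analysis of Knowledge Graph Embedding Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-triple topological analysis of directed multi-relational
    knowledge graphs (head/tail degrees, edge cardinality classes, and the
    symmetric, inference, inverse and composition edge patterns), together
    with shallow knowledge-graph-embedding models (TransE, DistMult, RotatE,
    TripleRE), filtered tail-prediction ranking with MRR and Hits@K, and
    stratified topology-versus-accuracy analyses. Includes a synthetic graph
    generator that plants ledgered pattern instances with controlled degree
    skew, so detectors, models and analyses can be validated end to end, and
    a paired case-study protocol for comparing models trained on two graphs
    that share a set of triples. Aimed at biomedical knowledge graphs (genes,
    drugs, diseases, pathways) but applicable to any triple store.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
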
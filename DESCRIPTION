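Package: ehrembed
Title: Time-Sensitive Clinical Concept Embeddings from Longitudinal EHR
Version: 0.1.0
Authors@R:
    person("EHR", "Embeddings Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns dense vector representations of coded clinical concepts
    (ICD-9 diagnoses, medications, procedures) from longitudinal patient
    visit sequences, selecting training contexts by calendar time rather
    than by token position. Implements three learners sharing the same
    temporal context regimes: skip-gram with negative sampling, PPMI-SVD
    (positive pointwise mutual information followed by truncated singular
    value decomposition of a temporally segmented co-occurrence matrix),
    and a FastText-style model composing concept vectors from character
    n-grams of the code strings. Ships intrinsic evaluation metrics
    (in/out-cluster cosine distances, the Medical Conceptual Similarity
    Measure, nearest-neighbour queries), a seeded generator of synthetic
    longitudinal EHR corpora with ground-truth concept groups, JSONL and
    word2vec-text I/O, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
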
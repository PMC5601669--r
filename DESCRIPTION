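Package: mlatc
Title: Multi-Label Prediction of ATC Drug Classes by Ontology Similarity
    and Gaussian Kernel Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-label classification of drug compounds into the
    14 main ATC (Anatomical Therapeutic Chemical) classes. Drugs are encoded
    as 14-dimensional vectors of per-class maximum similarity scores, using
    either semantic similarity between chemical-ontology terms (Jaccard
    overlap of is-a ancestor closures over an OBO-format ontology) or
    Tanimoto similarity between hashed substructure fingerprints. A
    multi-label Gaussian kernel regression classifier turns feature vectors
    into per-class decision scores, and a hybrid dispatcher routes each query
    to the ontology-based predictor when the compound is covered by the
    ontology and to the fingerprint-based predictor otherwise. Includes
    Chou's five multi-label evaluation metrics, leakage-safe jackknife
    (leave-one-out) evaluation, kernel-width tuning, a seeded generator of
    synthetic ontologies and multi-label benchmarks, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
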
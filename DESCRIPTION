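Package: enzrxn
Title: Enzymatic Reaction Product Prediction with a Sequence-to-Sequence Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the products of enzyme-catalysed reactions,
    including stereochemistry, from substrate SMILES combined with a free-text
    description of the enzyme. Provides curation of enzyme-annotated reaction
    corpora (canonicalization, deduplication, product-grouped splitting,
    non-canonical SMILES augmentation), an atomic SMILES tokenizer and a
    byte-pair-encoding text tokenizer sharing one vocabulary, an
    encoder-decoder transformer trained under single-corpus, sequential or
    weighted multi-task transfer-learning regimes with a noam learning-rate
    schedule, beam-search decoding with confidence scores, and a full
    evaluation suite (top-k accuracy, invalid-SMILES rates, enzyme-name
    stratifications, confidence calibration). A bundled synthetic
    enzymatic-reaction generator emulates the structure of literature-derived
    biocatalysis datasets so the whole pipeline is exercisable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
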
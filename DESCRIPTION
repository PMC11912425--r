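Package: spose2afc
Title: Sparse Positive Similarity Embeddings from Triplet 2-AFC Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sparse, nonnegative similarity embeddings (SPoSE-style) to
    two-alternative forced-choice triplet similarity judgments, reconstructs
    full pairwise similarity matrices by marginalizing predicted choices over
    all triplet contexts, and provides the surrounding analysis pipeline:
    worker-level quality control for crowdsourced triplet data, noise-ceiling
    and chance-corrected accuracy estimation, similarity-matrix comparison and
    split-half reliability, within/between-class structure, few-shot linear
    SVM class decoding, dimension reproducibility across random restarts,
    per-image dimension pruning curves, an image-computable ridge-regression
    stage mapping image features to embedding dimensions, and a synthetic-data
    generator so the entire pipeline is testable without behavioral downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
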
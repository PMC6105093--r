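Package: hbgru
Title: Hierarchical Bi-Directional GRU Attention Networks for Biomedical Abstract Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Document triage of biomedical abstracts with a hierarchical
    bi-directional gated-recurrent-unit (GRU) network equipped with attention
    pooling at the word and sentence levels and a title shortcut connection
    that concatenates the title representation directly into the document
    feature vector. Includes the full pipeline: entity-aware preprocessing
    from PubTator-style annotation files (entity tag insertion, multi-word
    expression tokenization), word2vec-format embedding initialization,
    model training with Adam, L2 regularization, gradient-norm clipping and
    early stopping on development-set F1, stratified splits and k-fold
    cross-validation, precision/recall/F1 evaluation, and a synthetic-corpus
    generator with a plantable lexical class signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
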
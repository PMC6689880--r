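Package: lstmvoter
Title: Two-Stage Ensemble Sequence Labeling for Chemical Named Entity
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemical named entity recognition by stacking the label streams
    of several upstream sequence taggers into a bidirectional LSTM-CRF with
    character-level and feature-level attention. Provides CoNLL-style TSV and
    character-offset annotation I/O, an IOB codec with strict span-level
    precision/recall/F1 evaluation, a per-token majority-vote baseline, a
    peephole LSTM / additive attention / linear-chain CRF computational kernel,
    the full trainable voter model with seeded deterministic training, a
    synthetic corpus generator with simulated noisy annotators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
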
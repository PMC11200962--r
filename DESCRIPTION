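Package: gatedtab
Title: Gated Tabular Transformers for Clinical Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting adverse clinical outcomes from structured
    electronic health record tables with a Transformer whose self-attention
    and feed-forward branches are modulated by learned sigmoid gates.
    Includes leakage-safe preprocessing of mixed categorical, continuous and
    datetime columns, autoencoder pre-training of column embeddings, a
    reproducible training loop with early stopping, an evaluation suite for
    imbalanced binary classification (confusion matrices, precision, recall,
    F1, ROC/AUC, PR/AP), and a synthetic cohort generator with planted,
    optionally interaction-bearing, signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
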
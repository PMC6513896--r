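Package: selimi
Title: Semantic Linguistic Impairment Index from Narrative Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a latent semantic analysis (LSA) word space from a text
    corpus (windowed co-occurrence counts, log-plus-one weighting, truncated
    singular value decomposition, unit-norm word vectors), summarizes
    children's spoken narratives as unit vectors in that space, and scores
    each narrative's probability of originating from a child with
    developmental language disorder (DLD) via leave-one-out ridge logistic
    regression -- the Semantic Linguistic Impairment Index (SELIMI).
    Includes diagnostic-accuracy evaluation (sensitivity, specificity,
    likelihood ratios, exact binomial test, ROC/AUC), a topic-structured
    synthetic data generator for end-to-end validation, and a reproducible
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
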
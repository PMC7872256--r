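Package: ssner
Title: Semi-Supervised Transfer Learning for Low-Resource Named Entity
    Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for biomedical named entity recognition when labeled
    data in the target domain is scarce. Implements a BiLSTM-CRF sequence
    tagger over frozen word embeddings, transfer learning by pre-training
    on a large annotated source corpus followed by fine-tuning on a small
    labeled target set, and iterative confidence-thresholded self-training
    on the unlabeled remainder of the target corpus. Includes entity-level
    exact and partial precision/recall/F1 evaluation in the SemEval-2013
    task 9.1 style, CoNLL-style BIO corpus input/output, a seeded
    synthetic-corpus generator with controllable entity density, lexicon
    overlap and silver-standard label noise, and a command-line interface
    for running simulation scenarios end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
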
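Package: rxnsplits
Title: Out-of-Distribution Benchmark Splits and Evaluation for Reaction
    Product Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and auditing out-of-distribution
    train/test splits of reaction corpora (random, document-, author-,
    time-, and reaction-class-based), scoring ranked product predictions
    with strict, stereochemistry-agnostic and formula-level top-k
    accuracy, multi-round iterated prediction, and fingerprint-based
    train/test distribution-shift diagnostics. Includes a generator for
    literature-structured synthetic reaction corpora (documents, author
    teams, substrate-scope series, class popularity drift) and a simple
    template-retrieval baseline predictor so split-difficulty trends can
    be demonstrated end to end without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    Matrix,
    dplyr,
    graphics,
    igraph,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
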
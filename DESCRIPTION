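Package: reosig
Title: Rank-Based Gene-Pair Signatures for Tumour Tissue-of-Origin
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects gene pairs whose within-sample relative expression
    orderings (REOs) are stable across samples, compares stable-pair lists
    between datasets with a concordance score and a cumulative binomial
    test, selects a voting signature from pairs whose ordering reverses
    between two tumour classes (ranked by gene appearance frequency and
    average within-sample rank difference), and classifies individual
    samples by a strict majority vote over the signature pairs.  Because
    every statistic depends only on within-sample orderings, the whole
    pipeline is invariant to monotone transformations and additive batch
    effects, which makes the signatures portable across platforms.  Ships
    the published five-pair colorectal-versus-lung-cancer signature, a
    seeded synthetic-data generator with planted reversed pairs and
    metastasis-like admixture samples, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
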
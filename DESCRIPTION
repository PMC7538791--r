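Package: reosig
Title: Qualitative Gene-Pair Signatures from Within-Sample Relative
    Expression Orderings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and application of qualitative transcriptional
    signatures built from within-sample relative expression orderings
    (REOs) of gene pairs, in the style of top-scoring-pairs rank
    classifiers.  Provides stable-pair mining per sample class,
    reversal-gene-pair detection, rank-difference reversal scoring,
    forward selection of a minimal gene-pair panel under a majority-vote
    rule, frozen-signature classification of single samples, and
    evaluation (sensitivity, specificity, geometric mean, rank-sum AUC
    with bootstrap confidence interval).  Ships a published 12-pair /
    17-gene pancreatic-cancer signature and a synthetic-cohort generator
    with planted reversal pairs, configurable penetrance, and per-sample
    strictly monotone distortions, so every pipeline stage is testable
    against ground truth without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
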
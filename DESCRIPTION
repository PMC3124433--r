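Package: saarbg
Title: Application-Specific Background Models for Single Amino Acid Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and statistical modelling of single amino acid repeats
    (SAARs, homopolymeric runs) in protein sequences. Provides maximal-run
    decomposition and cumulative non-overlapping tract counts, exact expected
    run counts under Markov chains of orders zero to three, zero-inflated
    two-stage background models (a logistic presence gate followed by either a
    sparse Bayesian kernel regressor or a least-squares polynomial), repeated
    hold-out cross-validation with empirical p-values and Holm correction, and
    a repeat-enrichment test for signal peptides versus mature sequences. A
    seeded synthetic proteome generator with ground truth makes the whole
    pipeline testable without external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
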
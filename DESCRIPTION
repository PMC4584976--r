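Package: captriplet
Title: Paralog Screening of Target-Capture Loci and Triplet Coalescent
    Models of Population Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quality control of targeted-enrichment (hybrid
    capture) phylogenomic data and for coalescent inference of population
    divergence from triplets of samples.  Implements paralog screening of
    per-locus alignments via a coverage test and an outgroup
    delta-variation test, mapping-stringency scan metrics, base-call
    quality filtering, supermatrix concatenation with partition tables,
    and variable/parsimony-informative site statistics.  Fits a
    three-population divergence model to unrooted triplet site-pattern
    counts under an infinite-sites coalescent, compares nested models
    (two-population, polytomy, panmixia) by likelihood-ratio tests with
    profile confidence intervals, and computes the expected per-locus
    log-likelihood difference between models to determine how many
    unlinked loci are required to reject a simpler history.  A
    synthetic-data generator produces coalescent triplet loci,
    paralog-contaminated capture datasets, and candidate-locus tables
    with known truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    pracma,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
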
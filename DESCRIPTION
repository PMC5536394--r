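Package: gwasAudit
Title: Winner's Curse Correction and Replication Auditing for Two-Stage GWAS
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing internal replication in two-stage quantitative-trait
    genome-wide association studies from summary statistics alone. Implements the
    conditional maximum-likelihood correction of the Winner's Curse for effect
    estimates ascertained by a significance threshold, noncentral chi-square power
    to replicate per locus, exact Poisson-binomial goodness-of-fit tests of observed
    versus predicted replication counts at nominal and Bonferroni thresholds,
    decile-level fit diagnostics, power-matched subsampling null tests, paired ROC
    comparison of raw versus corrected predictors, allele-frequency-matched
    annotation enrichment tests, and a synthetic two-stage GWAS catalog generator
    with known ground truth for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
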
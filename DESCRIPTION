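Package: savmir
Title: Small RNA Profiling of Winged and Wingless Aphid Morphs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of two-condition insect small RNA
    sequencing libraries, built around the winged/wingless polyphenism of
    the grain aphid Sitobion avenae. Provides raw read cleaning through a
    digital filter cascade (3' adapter trimming, length, quality and
    sequence-composition filters, ncRNA and repeat subtraction), collapsed
    tag counting, miRNA identification and conserved/semi-conserved/novel
    classification with stem-loop hairpin validation by a nearest-neighbor
    folding model, digital differential expression by 2x2 chi-squared
    tests with Bonferroni correction and fold-change thresholds, relative
    quantification of qPCR CT tables by the comparative threshold
    (2^-ddCT) method, canonical seed-match (8mer, 7mer-m8, 7mer-A1) target
    site scanning with hypergeometric term enrichment, and a ground-truthed
    synthetic data generator so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
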
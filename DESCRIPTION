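Package: mrith
Title: Multi-Region Exome Intratumor Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multi-region whole-exome sequencing of
    solid tumors, modelled on surgically resected small cell lung cancer
    cohorts. Takes per-region somatic mutation calls, allele-specific copy
    number segments, purity/ploidy estimates and clinical outcomes, and
    computes post-calling somatic filters with cross-region mutation rescue,
    cancer cell fraction estimation with binomial-mixture clustering of
    mutations, SNV and CNV intratumor heterogeneity scores, whole-genome
    doubling detection by a permutation null, maximum-parsimony phylogenies
    from presence/absence matrices, mutation and copy-number timing,
    96-context mutational signature refitting, driver occurrence and dominant
    scores, and survival associations (best-cutoff dichotomization, log-rank,
    Cox). Includes a synthetic multi-region cohort generator with known
    clonal architecture for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    ape,
    pracma,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
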
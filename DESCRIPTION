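Package: cnvtrait
Title: Copy-Number Variant Association with Continuous Reading and Language Traits in Sibship Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for testing effects of copy-number
    variants (CNVs) on continuous reading- and language-related performance
    in family-structured cohorts. Provides CNV call quality control and
    annotation in the PennCNV convention (confidence, span, probe-count and
    exclusion-region filters, gap-based joining, gene/exon annotation, rarity
    classification against a reference CNV set), composite phenotype
    derivation (first principal component of reading/language measures, IQ
    adjustment, decile-based case/control labels), genome-wide CNV burden
    tests with one-per-sibship resampling, probe-wise association of binary
    CNV state and of log R ratio intensity with family-respecting permutation
    tests, sample-size-weighted meta-analysis across cohorts, two-tier
    consecutive-probe region detection, case co-segregation screening, and
    interval-permutation gene-set enrichment. A synthetic-data module
    generates sibship cohorts, probe manifests, gene models, CNV landscapes,
    array intensities and factor-structured phenotypes with plantable
    CNV-phenotype effects, so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
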
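Package: xassoc
Title: Extreme-Phenotype Case-Control Germline Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-cohort extreme-phenotype germline association pipeline
    for case-control genotype data: per-variant exact allelic testing on
    2x2 allele-count tables, exhaustive-subset gene-level burden
    meta-analysis with directional case/control subset signals, cross-cohort
    coherence validation of variants and variant-rich genes via the
    intersection-union test, hypergeometric gene-set enrichment, and
    cross-validated genotype classifiers on allelic-dose encodings.
    Includes a synthetic-data generator that emulates a paired
    discovery/validation extreme-phenotype cohort design with planted
    coherent risk and protective variants, so every stage is testable
    offline against a ground-truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
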
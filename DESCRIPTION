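Package: cnvburden
Title: Rare Copy-Number Variant Burden Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-wide rare copy-number variant (CNV)
    case-control burden analysis from SNP-array call tables. Reads
    PennCNV- and QuantiSNP-style call files, merges adjacent segments,
    forms a two-caller consensus, applies per-sample and per-call quality
    control, computes dataset-internal CNV frequencies with a reciprocal
    overlap rule and filters to rare (<0.5%) variants, annotates calls
    against gene models with flanking regions, compares per-sample burden
    statistics between groups with label-permutation empirical p-values
    (including site, sex, and age-tertile stratification), tests
    case-exclusive disrupted genes for gene-set enrichment (hypergeometric
    and EASE variants), quantifies copy number from qPCR Ct tables by the
    delta-delta-Ct method, and simulates synthetic cohorts with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
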
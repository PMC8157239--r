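Package: famvar
Title: Familial Germline Variant Prioritization for Small Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("famvar", "developers", email = "famvar@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing rare germline variants in small familial
    cancer cohorts sequenced alongside an unrelated reference group. Implements
    pedigree kinship and degree-of-relationship estimation, genotype-based
    relatedness (method-of-moments kinship and identity-by-descent segment
    detection on phased haplotypes), a tiered single-nucleotide variant filter
    cascade (within-family sharing, population-frequency and pool-of-normals
    filters, exonic windows, consequence and pathogenicity-consensus rules,
    CADD tiers, cross-family recurrence), structural-variant breakpoint-overlap
    grouping, candidate-locus scans, and familial-versus-reference cohort
    comparisons. A pedigree gene-dropping simulator generates fully synthetic
    cohorts with known ground truth so every stage can be exercised end to end
    without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
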
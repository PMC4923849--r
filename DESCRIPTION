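Package: stresswgbs
Title: Stress-Associated Differential Methylation from Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) between
    exposure groups from whole-genome bisulfite sequencing count data
    using local-likelihood smoothing and a variance-floored t statistic,
    estimates the false discovery rate by balanced group-label
    permutation, classifies DMRs as genetically influenced (gDMR) or not
    (ngDMR) via cis methylation-QTL correlation tests, quantifies DMR
    overlap with annotation tracks against a length-preserving shuffle
    null (z scores) and with array CpG catalogs, performs gene-set
    enrichment for DMR-associated genes, and reproduces the
    epidemiological layer of a perinatal stress-wheeze study (perceived
    stress quartiles, contingency and adjusted odds ratios, adjusted
    geometric-mean ratios, representativeness chi-square tests). A
    synthetic-data module generates bisulfite count tables, genotypes,
    annotation tracks and cohort tables with planted effects so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    IRanges,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
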
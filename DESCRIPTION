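Package: pedaSPU
Title: Adaptive Gene-Level Association Tests for Pedigree Data Under Linear
    Mixed Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Gene-based association testing for quantitative traits measured
    on related individuals. Fits a single covariates-only linear mixed model
    with a kinship random intercept, extracts per-SNP score statistics and
    their null covariance, and combines them with the adaptive sum of
    powered score (aSPU) family of tests using Monte-Carlo p-values. Includes
    genotype input from PLINK binary and VCF, variant filtering and
    MAF-based imputation, genetic relationship matrix estimation, gene-window
    SNP assignment, a genome-wide scan driver with Bonferroni control, and a
    pedigree simulator for power and type-I error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, GenomeWideAssociation, StatisticalMethod
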
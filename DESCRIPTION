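Package: spatgs
Title: Spatial Adjustment of Field Trials and Genomic Selection for Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection in plant breeding programs that
    field-test inbred lines in spatially heterogeneous trials. Provides
    marker quality control (minor-allele-frequency, missingness and
    inbreeding filters), EM imputation of missing genotypes under a
    multivariate-normal line model, kinship and principal-coordinate
    analysis, and linkage-disequilibrium r-squared. Plot-level phenotypes
    are adjusted with four competing models - incomplete blocks,
    row-by-column, and two moving-means covariate models - fitted by a
    built-in REML engine, with broad-sense heritability and residual
    field-map diagnostics. Genomic prediction uses GBLUP with additive
    (ridge-regression) and Gaussian kernels, evaluated by replicated
    seven-fold cross-validation and cross-environment training. A synthetic
    field-trial and genotype simulator with known truth supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
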
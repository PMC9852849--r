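Package: coldscreen
Title: Multi-Trait Cold-Tolerance Screening of Crop Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for screening crop germplasm panels for cold tolerance from
    replicated multi-trait phenotype trials. Simulates balanced
    genotype-by-treatment trials with configurable genotypic and residual
    covariance structure, estimates variance components by one-way
    expected-mean-squares ANOVA (broad-sense heritability, genetic advance,
    genotypic coefficients of variation), assembles phenotypic and genotypic
    variance-covariance matrices, computes the Smith-Hazel selection index
    over leaf injury and chlorophyll-fluorescence traits (cold tolerance
    index, CTI), ranks and categorizes genotypes into tolerance classes, and
    provides supporting trait analytics: cold/control stress ratios,
    significance-annotated Pearson correlation matrices, and principal
    component analysis of trait variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
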
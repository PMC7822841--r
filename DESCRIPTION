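Package: prscreen
Title: Polygenic Score Construction, Trait Screening and Case-Contrast Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing polygenic risk scores (PRS) from GWAS
    summary statistics (allele harmonisation, greedy LD clumping, P-value
    thresholding, weighted scoring), screening many behavioural traits for
    PRS association under covariate adjustment (PheWAS-style, with
    incremental variance explained and two-tier significance), contrasting
    PRS-quantile trait trends in the undiagnosed population against
    diagnosed medicated and non-medicated case groups, and deriving
    lifetime migration metrics from planar coordinates and a population
    density raster. Includes genotype quality control (missingness, MAF,
    Hardy-Weinberg, KING-robust kinship pruning, PCA, ancestry clustering)
    and a synthetic cohort generator implementing a liability-threshold
    disorder with four causal scenarios (horizontal pleiotropy, population
    structure, disorder-to-trait, trait-to-disorder) for validating every
    stage without access-restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
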
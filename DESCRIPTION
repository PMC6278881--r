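Package: prsct
Title: Polygenic Risk Scoring by Clumping and Thresholding with High-Resolution Threshold Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for polygenic risk score (PRS) analysis from
    GWAS summary statistics: SNP and sample quality control (exact Hardy-Weinberg
    test, method-of-moments kinship pruning), allele harmonization between summary
    statistics and a target genotype panel, greedy LD clumping, incremental
    multi-threshold scoring over a dense p-value grid ("high-resolution scoring"),
    covariate-adjusted association with continuous and binary phenotypes reporting
    incremental (Nagelkerke) R-squared, PRS-by-sex interaction tests, quantile-effect
    curves against a central reference quantile, non-centrality-based analytic power,
    and a synthetic cohort generator with known LD structure, heritability, genetic
    correlation and disease prevalence so that every stage is testable without
    access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
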
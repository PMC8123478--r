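Package: protmr
Title: Proteome-Wide Two-Sample Mendelian Randomization from Summary
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds genetic instruments from protein quantitative trait
    locus (pQTL) catalogs, harmonizes them against disease GWAS summary
    statistics, and estimates causal effects of circulating protein
    concentrations on disease risk with the inverse-variance-weighted
    (IVW) two-sample Mendelian randomization estimator.  Includes
    reference-panel linkage-disequilibrium computation and greedy
    r-squared pruning, Benjamini-Hochberg false discovery rate control
    over a full protein panel, approximate conditional analysis on known
    risk variants from summary statistics (COJO-style), a
    ground-truth-aware synthetic data generator for pQTL and case-control
    GWAS summary statistics, and an end-to-end pipeline with
    per-histotype subgroup analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
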
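Package: mrflora
Title: Two-Sample Mendelian Randomization for Gut Microbiota and
    Hyperemesis Gravidarum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for bidirectional two-sample
    Mendelian randomization (MR) of gut-microbiota taxon abundances against
    hyperemesis gravidarum from GWAS summary statistics. Provides instrument
    selection with the usual quality-control rules (p-value thresholding with
    a relaxed fallback, greedy LD clumping, palindromic-SNP removal, allele
    harmonization, variance-explained and F instrument-strength statistics),
    five causal estimators (inverse-variance weighted, MR-Egger, weighted
    median, weighted mode, simple mode) plus per-SNP Wald ratios, a full
    sensitivity suite (Cochran's Q, MR-Egger intercept, leave-one-out,
    MR-PRESSO), and a synthetic summary-statistics generator with known
    ground truth so every stage of the inference chain is testable at desk
    scale.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
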
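Package: targetmr
Title: Druggable-Genome Mendelian Randomization for Drug-Target Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian randomization
    (MR) over the druggable genome using cis-eQTL instruments. Implements
    instrument selection (genome-wide significance, minor-allele-frequency and
    instrument-strength filters, greedy LD clumping), allele harmonization of
    summary statistics, Wald-ratio and inverse-variance-weighted causal
    estimation with Cochran's Q heterogeneity and MR-Egger intercept pleiotropy
    diagnostics, MR-Steiger directionality filtering, reverse MR, Bayesian
    colocalization via approximate Bayes factors, tiered external replication
    with family-wise Bonferroni control, and a biomarker association scan.
    Ships a summary-statistics simulator with known ground truth (LD-aware
    cis-eQTL regions, binary disease outcomes, shared/distinct causal-variant
    and reverse-causation scenarios) so the full pipeline is testable without
    external genotype or GWAS downloads.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
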
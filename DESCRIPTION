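Package: methmarker
Title: Longitudinal DNA Methylation Biomarker Discovery for Metabolic
    Phenotype Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering CpG methylation
    biomarkers of the transition from metabolically healthy to unhealthy
    obesity in small longitudinal EPIC-array cohorts. Covers probe
    filtering (sex chromosomes, SNP-adjacent probes, detection p-value
    failures), beta-mixture quantile (BMIQ) normalization of Infinium
    type II design bias, beta/M-value transforms, a two-stage PCA
    variable-contribution selection of candidate CpG sites across two
    time points, per-site Kruskal-Wallis validation with direction
    calls, gene-level differential-methylation summaries, and backward
    stepwise logistic regression yielding odds ratios with confidence
    intervals. A synthetic-cohort generator with planted ground-truth
    effects makes every stage testable by parameter recovery.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
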
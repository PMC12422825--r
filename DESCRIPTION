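Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening with Synthetic GWAS Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian randomization
    (MR) screens of many exposures against many outcomes from GWAS summary
    statistics. Covers the full workflow: reading, quality control and allele
    harmonization of summary statistics; greedy LD clumping and instrument
    strength diagnostics (per-variant R-squared, F-statistic); the
    inverse-variance-weighted, weighted-median and MR-Egger estimators with
    Cochran's Q, leave-one-out and a resampling-based pleiotropy outlier test
    (PRESSO-style); Benjamini-Hochberg FDR gating within outcomes;
    bidirectional MR and replication logic; and post-hoc power for continuous
    and binary outcomes. A seeded synthetic GWAS generator with known ground
    truth makes every stage testable without external data.
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
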
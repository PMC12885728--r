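Package: mirmr
Title: Two-Sample Mendelian Randomization of Circulating miRNA Effects on Disease Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for two-sample Mendelian randomization of plasma
    circulating microRNA expression on disease outcomes from summary statistics
    alone. Provides readers and allele harmonization for eQTL and GWAS summary
    tables, instrument selection (cis/consequence filters, Benjamini-Hochberg
    FDR, F-statistics, greedy LD clumping), inverse-variance weighted and
    MR-Egger causal estimators, heterogeneity (Cochran Q), pleiotropy
    (Egger intercept) and leave-one-out diagnostics, multi-criterion causal
    calls with independent-cohort replication, and a synthetic
    summary-statistics generator for end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
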
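Package: mrmediate
Title: Two-Sample and Two-Step Mendelian Randomization with Mediation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: drug-target (cis) instrument selection with LD
    clumping and strength filtering, allele harmonization with palindrome
    removal, a suite of summary-data causal estimators (Wald ratio, fixed-
    and random-effects inverse-variance weighted, MR-Egger, weighted
    median, and mode-based estimators), heterogeneity and pleiotropy
    diagnostics (Cochran's Q, MR-Egger intercept, MR-PRESSO outlier
    detection, leave-one-out, funnel tables), and two-step mediation MR
    with delta-method confidence intervals for the mediated proportion.
    Includes a generator of synthetic three-trait GWAS summary statistics
    with known causal structure for validation and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
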
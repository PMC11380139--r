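Package: mrpipe
Title: Two-Sample Mendelian Randomization Pipeline for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization on GWAS
    summary statistics: reading, validation and allele harmonization of
    summary tables; instrument selection by significance thresholding, LD
    clumping, confounder exclusion and F-statistic filtering; the Wald ratio,
    inverse-variance weighted, MR-Egger, weighted-median and weighted-mode
    causal estimators with odds-ratio reporting; a sensitivity suite with
    Cochran's Q, the Egger intercept test, a simulation-based residual
    sum-of-squares outlier test (global, per-SNP and distortion components),
    leave-one-out analysis and funnel data; reverse-direction analysis;
    multivariable MR for direct effects adjusted for confounder exposures;
    two-step mediation MR with the product-of-coefficients decomposition; and
    a seeded synthetic GWAS generator with known truth for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
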
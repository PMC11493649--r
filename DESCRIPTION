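Package: mrscreen
Title: Bidirectional Two-Sample Mendelian Randomization and Bayesian Model
    Averaging for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    screens on GWAS summary statistics: instrument selection with
    distance-based clumping and a lenient-threshold fallback, allele
    harmonization with palindromic-variant removal, inverse-variance weighted,
    MR-Egger and weighted-median estimators with heterogeneity and pleiotropy
    diagnostics, leave-one-out sensitivity analysis, and multivariable MR via
    Bayesian model averaging (MR-BMA) with Q-statistic and Cook's-distance
    instrument-outlier detection and a single repeat-after-removal pass.
    Includes a summary-statistics simulator with stored ground truth for
    calibration and recovery testing, and a config-driven pipeline that runs
    the full screen-then-BMA workflow with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
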
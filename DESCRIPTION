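Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: instrument quality control and allele harmonization,
    inverse-variance weighted, MR-Egger and weighted-median estimators,
    Cochran's Q, leave-one-out, simulation-based outlier (MR-PRESSO style)
    and Steiger directionality diagnostics, multivariable MR, and two-step
    mediation analysis with bootstrap confidence intervals for the mediated
    proportion. Includes a synthetic multi-trait summary-statistics
    generator with known causal and mediation structure, and a pipeline
    that runs the full analysis from one configuration.
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
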
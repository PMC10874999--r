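Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization workflow for GWAS
    summary statistics: instrument selection (genome-wide significance
    screen, greedy LD clumping, weak-instrument F filtering, confounder
    blocklists), allele harmonization with palindrome handling, causal
    estimation by inverse-variance weighting (fixed and multiplicative
    random effects), MR-Egger regression and the weighted median, and
    sensitivity diagnostics (Cochran's Q, the Egger intercept test,
    MR-PRESSO outlier detection, the Steiger directionality test,
    leave-one-out and funnel-plot data). Includes a seeded generator of
    paired exposure/outcome summary statistics with known ground truth so
    every pipeline stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
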
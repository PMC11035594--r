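Package: mrgxe
Title: Screening Gene-Environment Interactions from GWAS and GWIS Summary
    Statistics via Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene-environment (GxE) interaction and environmental
    mediation by contrasting marginal genetic effects from a genome-wide
    association study (GWAS) with main effects from a genome-wide interaction
    study (GWIS). An inverse-variance-weighted slope is fitted through the
    marginal-vs-main effect cloud using independent instruments, iteratively
    removing outlying variants, and each variant's departure from the fitted
    line is tested as a pleiotropy-style chi-square statistic. Includes
    summary-statistics harmonization with allele alignment and QC, a two-step
    screen-then-confirm procedure with locus and independent-signal
    definition, individual-level fitting of the marginal and interaction
    models, closed-form theory for the expected slope under sample overlap,
    LD-score regression on residual effects to bound interaction plus
    mediation heritability, and simulation designs with type-I error and
    power evaluation.
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
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
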
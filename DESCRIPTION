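Package: selectmeta
Title: Weight-Function Selection Models for Selective Reporting Bias in
    Multi-Dataset Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly estimates per-marker effect sizes, between-study
    variances and shared stepwise-constant publication weight functions
    from large collections of published study results, by maximum
    likelihood.  Implements category-dependent weight functions (initial
    studies, early replications, late replications) including a
    sign-dependent model of the Proteus phenomenon, AIC-based model
    comparison against an unbiased baseline, per-allele log odds ratios
    from 2x3 genotype tables, and a simulator of selectively reported
    study corpora for validation by parameter recovery.
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
    tools,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
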
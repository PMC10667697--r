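Package: forageQG
Title: Quantitative Genetics of Multi-Environment Forage Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of randomized complete block design (RCBD) forage
    breeding trials run across years and irrigation regimes: per-environment
    and combined analysis of variance, variance-component estimation from
    expected mean squares, phenotypic and genotypic coefficients of
    variation, broad-sense heritability, genetic advance under truncation
    selection, phenotypic and genotypic trait correlations from mean
    cross-products, stepwise yield-photosynthesis regression with partial R2
    accounting, and two-way trait-profile clustering. Includes a synthetic
    multi-environment-trial generator with known ground truth so every stage
    of the pipeline can be validated by parameter recovery, plus drip
    irrigation depth utilities for deficit-irrigation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    ggplot2,
    optparse
Config/testthat/edition: 3
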
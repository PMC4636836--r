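Package: svclean
Title: Protected-Design Surrogate Variable Estimation and Expression Cleaning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates latent systematic heterogeneity (surrogate variables) in
    log2 gene-expression matrices under an explicitly protected biological
    model, removes it to produce "cleaned" data for visualization while
    preserving the protected effects, and provides the surrounding toolkit:
    quantile normalization, design-matrix construction including lifespan
    spline models with a birth offset, permutation-based estimation of the
    number of surrogate variables, iteratively re-weighted surrogate variable
    estimation, empirical-Bayes known-batch adjustment, moderated t-statistic
    differential expression, exploratory PCA diagnostics, and synthetic-data
    generators with full ground truth for stem-cell differentiation and
    lifespan brain-expression designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
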
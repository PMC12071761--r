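Package: nirdisc
Title: Discriminant Pipelines for Near-Infrared Spectra with Singular
    Within-Class Scatter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of plant-tissue storage time from near-infrared
    (NIR) absorbance spectra in the small-sample-size regime where the number
    of wavenumbers far exceeds the number of samples and the within-class
    scatter matrix is singular. Provides spectral preprocessing (standard
    normal variate, multiplicative scatter correction, Savitzky-Golay
    smoothing, and their pairwise combinations) with a strict
    fit-on-train/apply-on-test contract; four small-sample-size-safe linear
    discriminant feature extractors (approximate, common-vector,
    maximum-uncertainty and null-space LDA); a CART classifier built from
    Gini splitting with weakest-link cost-complexity pruning selected by
    cross-validation; an ordered-target-statistic categorical encoder and a
    seeded gradient-boosted tree classifier; stratified k-fold evaluation
    with pooled confusion-matrix metrics; and a synthetic NIR spectra
    generator emulating class-dependent absorption bands, multiplicative
    scatter, baseline drift and additive noise.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
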
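Package: scdv
Title: Differential Variability Analysis for Single-Cell RNA-Seq with a
    Mean-Corrected Over-Dispersion Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian hierarchical inference for single-cell RNA-seq count
    data with gene-specific mean and over-dispersion parameters, a joint
    semi-parametric regression prior (Gaussian radial basis functions with
    Student-t residuals) that removes the mean/over-dispersion confounding,
    and probabilistic differential tests on mean, over-dispersion and
    residual over-dispersion calibrated by the expected false discovery
    rate. Supports spike-in (vertical) and multi-batch no-spike-in
    (horizontal) experimental designs via adaptive Metropolis-within-Gibbs
    samplers, and ships a model-based simulator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
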
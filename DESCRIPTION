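Package: fermga
Title: Fermentation Medium Optimization with Feed-Forward Neural Networks
    and Genetic Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A response-surface modelling and optimization pipeline for
    submerged-fermentation media. Builds six-factor central composite
    designs, scales factor settings to [-1, 1], fits a single-hidden-layer
    feed-forward neural network surrogate by Levenberg-Marquardt least
    squares, assesses it with MSE/RMSE/MAE/MAPE and the squared Pearson
    correlation, and maximizes the fitted surface with a binary-encoded
    genetic algorithm. Ships a 50-run alpha-galactosidase production
    dataset, pairwise interaction-surface slices, and a synthetic
    quadratic-surface generator for end-to-end recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
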
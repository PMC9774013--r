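Package: ssacop
Title: Hybrid Singular Spectrum Analysis and Copula Forecasting of Heart-Rate Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Short-term forecasting of uniformly sampled heart-rate time
    series by a hybrid deterministic-stochastic model. Singular spectrum
    analysis (trajectory-matrix SVD, grouping, diagonal averaging and a
    recurrent linear forecast) extracts and extrapolates the deterministic
    trend; the serially dependent residual is modelled with bivariate
    Archimedean copulas (Clayton, Frank, Gumbel) fitted by maximum
    likelihood on rank-transformed lagged residuals and predicted by
    conditional (h-function) sampling. Includes a seeded generator of
    protocol-style running heart-rate signals, sliding-origin evaluation of
    mean absolute error per forecast horizon, CSV input/output and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
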
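Package: vegrestore
Title: Hybrid Rule-Tree / Recurrent / Attention Modelling of Vegetation
    Restoration Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting ecological-restoration outcomes from
    multivariate environmental time series, built around a hybrid
    architecture that chains a Cubist/M5-style rule-based regression tree
    (structured feature extraction), a two-layer bidirectional gated
    recurrent unit network (temporal learning), and scaled dot-product
    self-attention (aggregation over time steps).  Includes a synthetic
    generator for Qinghai-Tibet-Plateau-like monthly monitoring panels
    with known ground-truth structure, the preprocessing chain
    (interpolation of missing values, robust outlier removal, seasonal
    adjustment, frequency alignment, train-only standardization),
    chronological splitting and expanding-window time-series
    cross-validation, a training loop with early stopping, the RMSE /
    MAPE / R-squared / within-10-percent accuracy metric suite, paired
    model comparison, sampling-based Shapley-value feature attribution,
    and an irrigation dose-response analysis for arid sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
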
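Package: ftsf
Title: Seasonal Time-Series Forecasting by First-Order Fuzzy Transform
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasting of seasonal univariate time series by the TSSF1
    method: a polynomial trend is fitted and removed, the de-trended series
    is split into within-season phase blocks, and each block's fluctuation
    is approximated by a first-order fuzzy-transform (F1) regression on an
    h-uniform raised-cosine fuzzy partition, with the node count chosen
    adaptively under a MAD-MEAN stopping rule. Includes the order-0 and
    order-1 discrete fuzzy-transform machinery, forecast accuracy metrics
    (RMSE, MAPE, MAD, MAD-MEAN), the NWS/Rothfusz heat-index transform used
    to build apparent-temperature series from daily weather records, and a
    seeded synthetic-data generator emulating multi-year seasonal weather
    series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
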
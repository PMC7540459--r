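Package: fires2s
Title: Subseasonal-to-Seasonal Forecasting of Global Fire Emissions with
    Region-Specific ARIMAX Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A global fire-emissions forecasting system for 1-6 month
    (subseasonal-to-seasonal) lead times. Gridded monthly emissions are
    partitioned into fire cohesive regions by an iterative multi-resolution
    criteria test, regional anomalies are standardized with a bounded
    tanh transform, lagged ocean-climate-index and vapor-pressure-deficit
    predictors are selected by cross-correlation, and region-specific
    ARIMAX models (regression with ARIMA errors, AIC order selection) are
    fit and verified by walk-forward cross-validation against persistence
    and climatology baselines. Includes a synthetic-data generator with
    planted, recoverable structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ncdf4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
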
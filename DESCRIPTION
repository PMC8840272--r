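Package: vhyield
Title: Subregional Crop-Yield Prediction from Satellite Vegetation Health Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A four-step framework for forecasting annual crop yields from
    weekly satellite vegetation health indices. Computes the vegetation
    condition index (VCI) and thermal condition index (TCI) from gridded
    NDVI and brightness-temperature records, partitions an agricultural
    region into subregions of uniform index behaviour by spatial independent
    component analysis with split-half (ICA-by-blocks) model-order
    selection, assembles per-subregion crop-year predictor tables with
    detrended yield anomalies as responses, and trains per-subregion,
    per-season machine-learning models with optional principal-component
    predictor reduction and leave-one-out hyperparameter tuning. Includes a
    synthetic-data generator with planted spatial sources and known yield
    processes so that every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    ica,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml,
    zoo
Suggests:
    jsonlite,
    mclust,
    ncdf4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
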
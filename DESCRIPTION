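Package: kriglag
Title: Kriged Daily Precipitation and Lagged Mosquito Trap-Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links daily precipitation surfaces, interpolated from weather-station
    networks by kriging with an elevation drift, to Aedes aegypti trap outcomes in
    arid urban landscapes. Provides automatic variogram fitting, daily surface
    construction, 20-day lag realignment of precipitation to trap collection dates,
    per-lag univariate screening, LASSO presence/abundance model comparison scored
    by AUC-ROC and RMSE, global Moran's I of aggregated trap counts, and a
    low-precipitation-threshold estimate of the anthropogenic-water-supported
    mosquito fraction, together with a seeded synthetic-data generator emulating
    the statistical structure of such surveillance studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
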
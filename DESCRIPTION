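Package: emdcast
Title: Hybrid EMD-PSO-BPANN Forecasting of Monthly Health-Service Demand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts monthly count series such as hospital outpatient visits
    with a hybrid pipeline: empirical mode decomposition (EMD) splits the
    series into intrinsic mode functions and a residue, a three-layer
    feed-forward network is fitted to each component with lagged inputs, the
    initial weights and thresholds of every network are found by particle
    swarm optimization with linearly decreasing inertia and time-varying
    acceleration coefficients, and the component forecasts are superposed.
    Includes a seeded generator of outpatient-visit-like seasonal series,
    evaluation criteria (correlation, RMSE, MAPE, SSE) and seasonal
    fluctuation indices, tidy accessors and ggplot2 autoplot methods, and
    readers/writers for monthly-series CSV files.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
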
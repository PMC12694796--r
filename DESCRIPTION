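Package: hmrisk
Title: Heritage Microclimate Risk Indices for Indoor Air Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Heritage Microclimate Risk (HMR) indices from hourly
    indoor-environment time series: an exhibit-conservation index (HMR_E) built
    from range-mode indicators such as temperature, relative humidity and
    artificial light, and a human-health index (HMR_H) built from threshold-mode
    pollutants (CO2, formaldehyde, TVOC, particulate matter, air ions). Each
    index combines a mean-level component with a day-to-day oscillation
    component and classifies scores into risk bands. Also quantifies
    antimicrobial-treatment efficacy from plate colony counts (CFU per gram
    with censoring) and ships a synthetic sensor-data generator with diurnal
    cycles, seasonal drift, AR(1) noise and controllable exceedance events, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
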
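Package: pmhia
Title: Health Impact Assessment of PM2.5-Attributable Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mortality burden attributable to ambient fine
    particulate matter (PM2.5) above counterfactual air-quality thresholds.
    Implements the Global Exposure Mortality Model (GEMM) hazard-ratio
    function for non-communicable disease plus lower respiratory infection
    mortality, an AirQ+-style log-linear relative-risk model, abridged
    period life tables, and the full counterfactual pipeline: attributable
    deaths, years of life lost, loss of life expectancy at birth, rates per
    100,000, and uncertainty intervals, with district-to-province
    aggregation, zonal aggregation of gridded exposure surfaces, and a
    synthetic demography/exposure generator for fully reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    yaml,
    jsonlite,
    withr,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
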
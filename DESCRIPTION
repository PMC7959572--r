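Package: baikalsi
Title: Silicon Cycling, Wind-Driven Deep Ventilation and Diatom Community
    Change in Lake Baikal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs relative silicic acid utilization and supply in the
    photic zone of Lake Baikal from diatom silicon isotope (d30Si) records and
    biogenic silica mass accumulation rates, using an open-system isotope
    fractionation model with Monte Carlo uncertainty propagation. Computes an
    event-based cumulative Ekman transport index of wind-driven deep
    ventilation from surface wind time series, expressed as seasonal anomalies
    against a 1990-2000 baseline. Detects significant temporal change in proxy
    series with penalized-spline trends, a continuous-time AR(1) residual
    process and simultaneous confidence bands on the first derivative, plus
    breakpoint and between-period tests. Quantifies diatom community structure
    and its association with nutrient supply via PCA and partial redundancy
    analysis. Ships a synthetic-data generator with known truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    nlme,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
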
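Package: urban3d
Title: Three-Dimensional Landscape Metrics, Land-Use Regression and
    Geographically Weighted Regression for Urban PM2.5
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how the three-dimensional form of urban
    land-function zones relates to fine particulate matter (PM2.5).
    Provides a seeded synthetic-city generator (parcels, buildings,
    roads, monitoring panel), identification of residential, commercial,
    industrial and educational function zones from land-use composition,
    six 3D landscape pattern indices of built form (height density,
    volume density, spatial dispersion, fluctuation, building diversity
    and uniformity), land-use regression (LUR) with buffer-based
    predictor extraction, correlation screening, iterative stepwise
    fitting and hold-out validation, raster prediction of the PM2.5
    surface, zonal statistics with one-way ANOVA and LSD post hoc
    comparisons, and geographically weighted regression (GWR) with AICc
    bandwidth selection and Moran's I residual diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
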
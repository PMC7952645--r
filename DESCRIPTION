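Package: pwcspec
Title: Plant Water Content Estimation from Canopy Hyperspectral Reflectance
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A chemometrics workflow for estimating plant water content
    (PWC, percent of dry weight) of winter wheat from canopy reflectance
    spectra (350-2500 nm). Provides a synthetic canopy-scene generator that
    emulates a two-season irrigation trial with planted water-absorption
    features; Savitzky-Golay smoothing, spectral trimming and water-vapor
    masking; nine spectral transformations (reciprocal, log-reciprocal,
    first derivatives, continuum removal, multiplicative scatter
    correction, peak normalization); single-response partial least squares
    regression with leave-one-out cross-validation, B-coefficients and VIP
    scores; band selection by a B-coefficient/VIP screen combined with
    stepwise regression, the successive projections algorithm, random frog
    and uninformative variable elimination; and model evaluation by R2,
    RMSE and the ratio of performance to interquartile distance (RPIQ).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
VignetteBuilder: knitr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
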
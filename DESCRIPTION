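Package: nitraspec
Title: Hyperspectral Estimation of Petiole Nitrate Nitrogen in Cotton
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates nitrate-nitrogen concentration in cotton petioles
    from canopy reflectance spectra (350-1075 nm). Provides spectral
    ingestion and scan averaging, first-derivative preprocessing,
    trilateral edge parameters and red-edge vegetation indices,
    correlation and single-feature regression screening, a from-scratch
    wavelet neural network estimator with hidden-node selection, random
    forest / radial basis function / back-propagation baselines, the
    accuracy metrics and percent-change arithmetic used to compare them,
    and a seeded synthetic canopy-spectrum generator emulating the field
    design so the whole analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    randomForest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
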
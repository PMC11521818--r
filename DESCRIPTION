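Package: chlorospec
Title: Leaf Chlorophyll Estimation from Proximal Hyperspectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for estimating maize leaf chlorophyll
    content (a+b, ug/g fresh weight) from 400-1000 nm leaf reflectance
    spectra. Provides a seeded synthetic spectra generator with a
    chlorophyll-dependent red edge, the Arnon spectrophotometric
    determination, eleven red-edge and green-region vegetation indices
    (including the CHLI1-3 chlorophyll indices built on 516, 551 and
    763 nm), wavelength selection by PCA with Varimax rotation and
    relative-standard-deviation profiling, variance inflation factor
    collinearity screening, a minimum-redundancy maximum-relevance
    (MRMR) feature ranker built from mutual information, six regression
    model families (Huber robust linear, stepwise linear with
    interactions, quadratic-kernel and fine-Gaussian epsilon-SVR,
    Matern 5/2 Gaussian process regression, and a three-hidden-layer
    ReLU network), and an evaluation layer reporting R2, RMSE, MAE,
    mean bias deviation and mean squared prediction error over
    every-third-record and random train/validation splits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
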
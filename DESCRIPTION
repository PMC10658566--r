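Package: mnperm
Title: Simulation and Statistical Prediction of Drug Permeation Through
    Microneedle-Treated Skin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic and statistical modelling of transdermal drug
    delivery through microneedle-treated skin. Provides a two-dimensional
    explicit finite-difference (FTCS) solver for Fick's second law over a
    needle-skin-receptor unit cell, microneedle patch geometry (frustum and
    square-pyramid surface areas, grid rasterization), readers and
    validators for Franz-cell permeation datasets, multiple linear
    regression and tree-ensemble (random forest, gradient-boosted trees)
    predictors of cumulative permeation amount and percentage, RMSE/R-squared
    model comparison with leave-one-drug-out validation, and a synthetic
    dataset generator that drives every stage from the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    randomForest,
    xgboost,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
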
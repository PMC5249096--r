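Package: sptmotion
Title: Motion-Type Classification and Segmentation of Single-Particle
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for single-particle tracking analysis: Monte-Carlo
    simulation of the four basic motion types (normal, anomalous and
    confined diffusion, and directed motion), mean squared displacement
    analysis and model fitting, a nine-feature random-forest classifier
    trained on simulated trajectories, and sliding-window segmentation of
    experimental trajectories into labelled motion-type segments with
    confidence levels and fitted motion-model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    optparse,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
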
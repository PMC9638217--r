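Package: ssdfs
Title: Wrapper Feature Selection with the Social Ski-Driver Optimizer
    and Adaptive Beta Hill Climbing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary wrapper feature selection for labeled feature tables,
    built around the Social Ski-Driver (SSD) swarm optimizer with an
    embedded Adaptive Beta Hill Climbing (ABHC) local search. Candidate
    feature subsets are scored by a k-nearest-neighbour classifier on a
    stratified hold-out split, combining classification error with subset
    size in a single weighted fitness. Includes a V-shaped transfer
    function binarization, an exhaustive subset oracle for desk-scale
    verification, a synthetic feature-table generator with known
    informative, redundant and noise features, an attention-weighted
    global-average-pooling convolutional feature extractor for grayscale
    images, a multi-run evaluation protocol (mean and standard deviation
    over simulations), and an exact/approximate Mann-Whitney U test for
    comparing methods.
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
    jsonlite,
    parallel,
    png,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
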
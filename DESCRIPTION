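Package: voxkern
Title: Voxel-Wise Visual Encoding Models with Mixed Large- and Small-Kernel
    Convolutional Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds voxel-wise encoding models of visual cortex fMRI responses
    from convolutional image features. Implements two feature extractors on a
    pure-CPU engine - a small-kernel VGG16-style network and a large-kernel
    RepLKNet-style network with structural-reparameterization kernel fusion -
    merges their multi-layer activations into a mixed feature space, reduces it
    by principal component analysis, and fits per-voxel sparse linear models by
    regularized orthogonal matching pursuit (ROMP). Predictions are scored by
    Pearson correlation with a validity threshold and summarized per region of
    interest. Also quantifies effective receptive fields (ERF) of the
    extractors as input-pixel contribution heatmaps, and ships a synthetic
    stimulus-response generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
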
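Package: libsclass
Title: Chemometric Classification of Non-Gated LIBS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying laser-induced breakdown
    spectroscopy (LIBS) emission spectra recorded without detector gating,
    where a broad continuum background accompanies the characteristic atomic
    lines. Provides spectral preprocessing (laser-notch masking, reference
    hydrogen-line normalization), iterative constrained-polynomial continuum
    removal, dendrogram-based outlier detection, principal component
    analysis, soft independent modelling of class analogy (SIMCA) with a
    3-sigma residual acceptance threshold, partial least squares
    discriminant analysis via NIPALS, a small neural-network classifier, and
    a stratified resampled evaluation protocol with trichotomy
    (correct/misclassified/unclassified) rates. A forward simulator of LIBS
    spectra (Gaussian lines, smooth continuum, shot and fixed-pattern noise,
    pellet-inhomogeneity scatter) makes every stage verifiable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
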
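Package: ordinalPRF
Title: Population Receptive Field Modeling of Ordinality Tuning in Brains and Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate neural tuning to ordinal position (1st, 2nd, 3rd, ...)
    from fMRI time series and from convolutional network activations. The fMRI arm fits a
    log-Gaussian population receptive field (pRF) model of ordinality per recording site,
    with two-gamma hemodynamic convolution, subject-level HRF re-estimation,
    cross-condition validation and group-level permutation statistics on tuning width and
    cortical coverage. The network arm builds a hierarchical convolutional architecture,
    generates factorial snake-stimulus image sets, screens units for ordinality
    selectivity with a balanced two-way ANOVA, pools and fits tuning curves, and decodes
    rank with a support vector machine. A synthetic-data module provides seeded
    ground-truth generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    minpack.lm,
    png,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
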
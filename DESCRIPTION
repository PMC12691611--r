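Package: mxquant
Title: Quantitative Analysis of Bacterial Surface Motility, Fluorescence
    Colocalization, and Equilibrium Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying type IVa pilus-driven single-cell motility
    of rod-shaped bacteria from time-lapse microscopy: capsule-cell movie
    simulation with ground truth, threshold/moment based detection, globally
    optimal frame-to-frame track linking, instantaneous velocity profiling,
    cumulative surface-coverage rasters and Gaussian-smoothed density
    heatmaps. Also computes Manders, Pearson and intensity-correlation
    colocalization statistics from two-channel fluorescence images, and fits
    1:1 equilibrium binding models to surface plasmon resonance steady-state
    responses and isothermal titration calorimetry thermograms, with paired
    synthetic-data generators for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
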
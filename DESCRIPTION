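Package: scentpipe
Title: Debiased GC-MS Scent-Character Analysis for Urine Volatilomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Preprocessing, debiasing and image-based classification of
    GC-MS ion chromatograms for urinary volatile-organic-compound profiling.
    Implements m/z binning, segmented quantile noise subtraction, iterative
    polynomial baseline drift correction, internal-standard (Mirex)
    normalization, empirical-Bayes source-batch correction with a gamma prior
    on multiplicative effects and a normal prior on additive shifts,
    fixed-size image encodings of chromatograms, a domain-adversarial
    convolutional classifier with a gradient-reversal layer, residual-bias
    probes, and stratified cross-validation reporting. A synthetic
    chromatogram generator with ground truth supports end-to-end testing
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    fitdistrplus,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse
biocViews: MassSpectrometry, Metabolomics, BatchEffect, Classification,
    Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
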
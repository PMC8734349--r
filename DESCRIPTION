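Package: t1net
Title: Accelerated Cardiac T1 Mapping with Neural-Network and Curve-Fit
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative myocardial T1 mapping from Look-Locker
    inversion-recovery acquisitions.  Implements the MOLLI acquisition-scheme
    grammar and inversion-time arithmetic, the three-parameter
    inversion-recovery signal model with Look-Locker correction, a per-pixel
    nonlinear curve-fitting baseline with polarity restoration, a small fully
    connected neural network that estimates T1 from four or five T1-weighted
    samples of a single Look-Locker experiment, synthetic training data and
    digital phantom generators, and the agreement statistics (ROI summaries,
    Bland-Altman analysis, extracellular volume fraction) used to validate
    accelerated T1 mapping against the MOLLI reference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
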
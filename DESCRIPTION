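Package: twinlocal
Title: Twin Modelling of Local Resting-State fMRI Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying genetic and environmental influences on local
    resting-state fMRI metrics in twin cohorts. Computes framewise
    displacement, motion scrubbing, confound regression, detrending, bandpass
    filtering, voxelwise regional homogeneity (Kendall's coefficient of
    concordance) and fractional amplitude of low-frequency fluctuations,
    Z-standardization, Gaussian smoothing and atlas ROI extraction. Fits
    saturated and bivariate Cholesky-decomposed ACE twin models across two
    longitudinal waves by full-information maximum likelihood, with
    likelihood-ratio tests, AIC model selection, profile-likelihood confidence
    intervals and genetic and environmental correlations, plus random-intercept
    mixed models for brain-behavior associations and Benjamini-Hochberg false
    discovery rate control. Includes a synthetic-data generator with known
    ground truth so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    lme4,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
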
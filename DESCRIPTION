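Package: eegdecode
Title: Multiscale Feature Extraction and Time-Resolved Decoding of Epoched EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved multivariate decoding of epoched multi-channel EEG
    from a library of 26 window-level time-series features (moments, median,
    Lempel-Ziv complexity, fractal dimensions, Hurst exponent, entropies,
    autocorrelation, Hjorth parameters, spectral summaries, cross-correlation,
    Symlet-2 wavelet coefficients, Hilbert amplitude/phase, and raw samples).
    Features are extracted from short sliding windows, equalized in dimension
    by training-fold principal component analysis, optionally combined through
    feature-selection algorithms (Fisher score, mutual information, mRMR,
    ReliefF, lasso, Laplacian score, CFS), and decoded with pairwise
    shrinkage-regularized linear discriminant analysis under stratified
    cross-validation. Statistical evaluation includes JZS Bayes-factor
    evidence series against the pre-stimulus baseline, decoding-curve
    parameters, and permutation-tested Spearman correlation between decoding
    and reaction times with positive false-discovery-rate correction. A
    seeded synthetic-cohort generator produces epoched trials whose category
    information is carried by configurable encoding codes (mean, variance,
    frequency, or multiscale wavelet bursts) for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pracma,
    yaml
Config/testthat/edition: 3
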
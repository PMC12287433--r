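Package: myospect
Title: Rotation-Invariant Spectral Features for Early Prediction of
    Myogenic Differentiation Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for early, non-destructive prediction of muscle
    stem cell differentiation efficiency from phase-contrast microscopy.
    Provides a seeded synthetic plate generator emulating the
    well/day/position imaging hierarchy of a differentiation experiment,
    rotation-invariant feature extraction by radial shell integration of
    the FFT power spectrum, a reduced-dimension (PCA plus one-component
    PLS-DA) random-forest classifier of high/low efficiency outcome,
    well-grouped repeated cross-validation with AUC summaries and
    nonparametric day comparisons, and manufacturing-filter metrics
    (false positive/negative rates and impurity change).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
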
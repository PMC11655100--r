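Package: ecglvh
Title: ECG-Based Detection of Left Ventricular Hypertrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-based detection of left ventricular hypertrophy (LVH)
    from standard 12-lead electrocardiograms. Provides a seedable synthetic
    12-lead ECG generator with analytic ground-truth fiducials, WFDB record
    input/output, beat detection and wave delineation with beat-quality
    control, three feature families (19 morphological features per lead,
    a 4-term Hermite-function decomposition of the averaged QRS complex,
    and the V-index of spatial repolarization heterogeneity), a battery of
    22 codified clinical voltage criteria and their any-of combinations,
    and a machine-learning pipeline with sequential floating forward
    selection, class-balanced cross-validated training of logistic
    regression, random forest and support vector machine classifiers,
    ROC-distance threshold optimization and majority-vote ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
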
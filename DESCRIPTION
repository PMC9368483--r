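Package: retinox
Title: Retinal Hemodynamic and Oxygen Metrics from Phosphorescence
    Lifetime Oximetry and Microsphere Velocimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification chain for retinal vascular physiology in
    two-group (wild-type versus 5XFAD transgenic) mouse studies: estimates
    phosphorescence lifetime from frequency-domain traces and converts it
    through the Stern-Volmer relation and the hemoglobin dissociation curve
    to vascular oxygen tension, saturation and blood oxygen content;
    measures venous blood velocity from fluorescent microsphere tracks and
    vessel caliber from angiographic cross-profiles; derives per-eye flow
    (TRBF), oxygen delivery, metabolism and extraction fraction, and retinal
    layer morphometry; and computes cohort statistics (pooled t-tests,
    Pearson correlations, post-hoc power by noncentral t and the exact
    bivariate-normal distribution of the correlation coefficient). Includes
    a calibrated synthetic-cohort generator emitting both truth-level
    metrics and raw-style signals for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
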
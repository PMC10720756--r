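Package: lordprog
Title: Quantitative Natural History of Late-Onset Retinal Degeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying disease progression in C1QTNF5-associated
    late-onset retinal degeneration (LORD) from fundus autofluorescence (FAF)
    and optical coherence tomography (OCT) derivatives. Provides anatomically
    normalized superpixel atrophy maps (shear alignment of fovea and optic
    nerve head, fixed 20-superpixel fovea-disc spacing), projective
    control-point registration of follow-up images, circle-restricted area of
    atrophy with square-root transform, ellipsoid-zone width and foveal
    thickness extraction, LogMAR conversion, and longitudinal inference:
    linear mixed models with patient and eye random intercepts,
    piecewise-linear (hinge) breakpoint estimation with patient-bootstrap
    confidence intervals, repeated-measures correlation, and age-stratified
    spatial prevalence maps. A fully synthetic longitudinal cohort generator
    with known ground truth supports validation and parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
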
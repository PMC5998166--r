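Package: noderadiomics
Title: Morphological and Enhancement-Curve Radiomics for Axillary Lymph Nodes
Version: 0.1.0
Authors@R: person("Node", "Radiomics Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative assessment of axillary lymph nodes on dynamic
    contrast-enhanced MRI. Computes seventeen morphological descriptors from
    3D binary volume-of-interest masks (isotropically resampled to 1 mm
    voxels) and nine model-free enhancement-curve features from 5-point
    signal-time curves, and provides the accompanying statistical layer:
    Mann-Whitney group comparison, per-feature ROC operating-point analysis,
    Fisher linear discriminant analysis with stratified k-fold
    cross-validation, and two-reader ICC(2,1) agreement. Includes a
    calibrated synthetic lymph-node phantom cohort generator (star-shaped
    spherical-harmonic perturbed ellipsoids plus piecewise-linear enhancement
    curves) so the full pipeline runs end-to-end without clinical data, and a
    command-line pipeline orchestrator with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
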
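# noderadiomics

Quantitative assessment of axillary lymph nodes on dynamic contrast-enhanced
(DCE) breast MRI. Preoperative, non-invasive staging of the axilla matters
for surgical planning, yet visual criteria for nodal malignancy remain
contested; this package implements the quantitative alternative — shape
radiomics of the segmented node plus semi-quantitative enhancement-curve
analysis — as a reusable, fully tested R pipeline for radiologists and
imaging scientists who have per-node VOI masks (NIfTI) and signal-time
curves (CSV) and want the complete descriptive and discriminative analysis.

## What it computes

**Morphology** (on the binary VOI mask, resampled to 1 mm isotropic voxels):
volume `V` (voxel count x 1 mm³), surface (boundary-voxel count),
equivalent-sphere diameter `2(3V/4π)^{1/3}`, compactness `A/V` (A =
exposed-face area), circularity `(4/3)πμ³/V` and irregularity `1 − 4πμ²/A`
(μ = mean boundary-to-barycentre distance), radial length `μ/max Rₙ`,
spiculation `sd(Rₙ)`, sphericity `μ/sd(Rₙ)`, roughness
`(m₄^{1/4} − m₂^{1/2})/μ`, radial entropy `−Σ p ln p`, per-slice contour
curvature `mean |x′y″ − y′x″|/(x′²+y′²)^{3/2}` and smoothness
`mean |Rₙ − (Rₙ₋₁+Rₙ₊₁)/2|`, rectangularity `V/bbox`, eccentricity (longest
chord over longest perpendicular chord), elongation (mean in-slice bounding
rectangle side ratio over three axis directions), convexity `hull(V)/V`.

**Dynamics** (on the 5-point, 90 s signal-time curve): time to peak (TTP),
maximum signal difference (MSD), wash-in/wash-out slope and intercept
(WIS/WII, WOS/WOI; OLS on the rising and falling segments, peak shared),
and trapezoidal areas AUGC, AUCWI, AUCWO with AUGC = AUCWI + AUCWO.

**Statistics**: Mann-Whitney (exact for small untied samples), per-feature
ROC with Youden (or accuracy) operating points, Fisher LDA with stratified
10-fold cross-validation, and two-reader ICC(2,1) with an F-based 95% CI —
emitted as four report tables (group medians/SDs + p; per-feature ROC; LDA
of feature sets including the "accuracy > 70%" subsets).

A calibrated synthetic phantom generator (spherical-harmonic-perturbed
ellipsoids + piecewise-linear enhancement curves, two simulated readers)
exercises everything end-to-end with no external data; see the methods
vignette (`vignettes/node-radiomics-methods.Rmd`) for the model, every
default, and known limitations.

## Worked example

```r
library(noderadiomics)

cfg <- list(synthetic = list(n_metastatic = 10, n_nonmetastatic = 10),
            folds = 5, seed = 17)
run_pipeline(cfg, "run1", seed = 17)

head(read.csv("run1/report/table4.csv")[,
     c("feature", "sensitivity", "specificity", "accuracy", "auroc")], 8)
#>   feature sensitivity specificity accuracy auroc
#> 1     TTP          30        90.0     60.0 0.565
#> 2     MSD          70        70.0     70.0 0.660
#> 3     WIS          40       100.0     70.0 0.640
#> 4     WII         100        30.0     65.0 0.610
#> 5     WOS          50       100.0     71.4 0.583
#> 6     WOI          75        66.7     71.4 0.667
#> 7    AUGC          70        70.0     70.0 0.630
#> 8   AUCWI          60        60.0     60.0 0.520
```

Each row is one enhancement-curve feature scored as a single-feature
classifier of metastatic vs nonmetastatic nodes on the 20-node synthetic
cohort: the operating point (Youden-optimal) gives the printed
sensitivity/specificity/accuracy in percent, `auroc` the
threshold-independent separation. Rows where the wash-out segment was
missing (curves peaking at the last acquisition) are computed on the nodes
that have one — WOS/WOI rest on the 7 of 20 nodes with an observable
wash-out here (`n_missing = 13` in the table).

Two-reader agreement on the same run:

```r
morph <- read.csv("run1/features_morph.csv")
v1 <- morph$volume[morph$reader_id == "reader1"]
v2 <- morph$volume[morph$reader_id == "reader2"]
interobserver_icc(v1, v2)
#> volume ICC 0.741 (95% CI 0.457-0.889, good)
```

At this small n the CI is wide; the default 94-node cohort lands in the
"excellent" band (~0.86), matching the agreement the method is calibrated
to emulate.

The same stages are available on the command line:

```sh
nodal-radiomics simulate --out cohort --seed 17
nodal-radiomics extract-morph --masks cohort/masks --out features_morph.csv
nodal-radiomics extract-dyn --curves cohort/curves.csv --out features_dyn.csv
nodal-radiomics analyze --features features_dyn.csv --labels cohort/labels.csv \
    --out report --folds 10 --seed 17
```

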
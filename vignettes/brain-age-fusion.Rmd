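---
title: "Multimodal brain age prediction and the brain age gap: models and methods"
author: "neuroBAG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal brain age prediction and the brain age gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Biological brain age is the age a predictive model reads off a brain scan.
Its difference to the chronological age — the brain age gap (BAG) — is a
compact biomarker of deviation from normal aging: a positive gap means an
older-looking brain. Two families of predictors dominate the field:
classical regressors on hand-crafted morphometry (structure volumes,
surface areas, cortical thickness, artery diameters), and 3D convolutional
networks reading the preprocessed image directly. `neuroBAG` implements
both families for two modalities (T1-like structural images and TOF-MRA-like
angiography), fuses them by stacked linear regression, corrects the
well-known age-related bias of such models, and regresses the resulting BAG
on cardiovascular risk factors.

Real cohorts of this kind are access-restricted, so the package is built
around a synthetic-data module that generates cohorts, feature tables and
phantom volumes with *known* age and risk-factor structure. Every
downstream stage is therefore testable end-to-end, with parameter-recovery
oracles instead of inaccessible reference data.

# The synthetic cohort

`generateCohort()` draws ages from a truncated normal on 21-81 years whose
*observed* mean and sd match the published 49.9 (13.7) — cohort tables
report the moments of the bounded sample, so the parent normal is
recovered by moment matching — sex from a Bernoulli (909/1658 female), systolic blood
pressure from N(126.0, 16.4) mmHg, BMI from N(27.3, 4.2) kg/m², a
sex-conditional waist-to-hip ratio (N(0.82, 0.06) women / N(0.94, 0.07)
men), and ordinal smoking (five levels, weights 668/56/347/266/321) and
alcohol (four levels, 112/458/963/125) categories. These defaults mirror
the demographic table of the mid-size population cohort the package
emulates. Risk factors are independent of age by default; a Gaussian
copula on the latent normal scale injects configurable age correlations,
since only marginals are published for such cohorts.

The scientifically load-bearing choice is the **hidden biological brain
age**: each subject carries an offset δ composed of risk-factor effects
(defaults: +0.8 years per sd of BMI, +0.7 per sd of WHR, +0.6 per sd of
blood pressure — the magnitude range reported for such associations) plus a
residual with sd 5 years. Every synthetic brain *looks* `age + δ` old, in
all modalities. This term is what keeps age decoding imperfect at a
realistic 4-6 years MAE (a generator without it lets models decode
chronological age almost exactly, which no real cohort shows), and it is
what gives the BAG genuine associations for the final stage to find.
`biologicalAges()` exposes it for oracle tests.

# Feature tables and phantoms

**T1 morphometry.** `generateMorphometry()` produces the 223-column table of
a cortical/subcortical segmentation pipeline: 64 cortical structures × 3
measures (area, gray volume, thickness) + 30 subcortical volumes + total
brain volume. Only the total of 223 is fixed by the emulated protocol; the
name list is a plausible naming shipped as
`inst/extdata/t1_feature_schema.txt`. Each feature is affine in biological
age, sex and standardized risk factors, plus a shared per-subject head-size
factor (loading on volume/area features) and independent Gaussian noise.
Volumes and thicknesses shrink by roughly 0.5-1.5% of scale per decade;
ventricular and CSF spaces grow; male offsets apply to volumes and areas
only. With noise and latent factors set to zero the features are exactly
linear — the basis of the package's machine-precision recovery tests.

**T1-like phantom volumes.** An ellipsoidal bright tissue shell with a
central ventricle whose semi-axes grow with biological age
(0.0022 of the grid per year, about a voxel per decade at 48³) while the
outer shell shrinks slowly; per-subject anatomical jitter (sd 0.008 of the
grid) plus voxel noise; intensities center scaled to zero mean and unit sd
over the whole grid, as image preprocessing would do. No radiological
realism is attempted — the phantom exists so that a convolutional network
has a spatially localized, monotone age signal to find, which the saliency
tests then verify it found *there*.

**TOF-like phantoms and the atlas.** `makeRoiAtlas()` partitions the brain
mask into six flow territories (ACA/MCA/PCA × left/right: hemisphere split
at the x midline, anterior/middle/posterior thirds in y) and places eleven
artery-segment ROIs as tubes around fixed polyline centerlines (PCA L/R,
MCA-M1 L/R, MCA-M2 L/R, BA, ICA L/R, ACA-A1, ACA-A2). The printed total of
24 artery features forces 11 segments; we resolve the enumeration by
treating the basilar artery and both ACA segments as unlateralized midline
structures, and keep the schema configurable since the exact split is not
published. `generateVesselVolume()` draws bright tubes whose radii shrink
by 0.02 voxels/year from segment-specific baselines (2.2-3.2 voxels at
48³), with per-subject radius jitter (sd 0.25 voxels) and a hard clamp at
1 voxel (warned, since the signal saturates there). Tubes are drawn around
paths extended 6 voxels beyond each ROI end: a distance transform
underestimates radii at free tube ends, and real arteries continue beyond
any labeled segment, so in-ROI centerline voxels should see interior
geometry.

# Vessel morphometry

The measurement chain is segmentation → centerline → thickness →
aggregation:

* `segmentVessels()`: intensity threshold at mean + k·sd (default k = 2)
  and removal of 26-connected components below 10 voxels. The published
  pipelines use level-set segmentation with vesselness enhancement; on
  high-contrast phantoms thresholding is sufficient, and the downstream
  interface accepts any externally produced mask.
* `extractCenterline()`: sequential topology-preserving thinning. A voxel
  is deletable iff it is *simple* (its 26-neighborhood holds exactly one
  26-connected foreground component and its 18-neighborhood exactly one
  6-connected background component touching the voxel) and not a curve
  endpoint (≤ 1 foreground neighbor). Border voxels are processed per face
  direction in increasing distance-transform order — the ordering is what
  keeps the skeleton centered — with re-checking before each deletion, so
  connectivity is preserved by construction.
* `computeThickness()`: exact Euclidean distance transform
  (Felzenszwalb-Huttenlocher lower-envelope, separable, honoring
  anisotropic spacing) from each mask voxel to the nearest **background
  voxel center**; the grid boundary counts as background. Under this
  convention an isolated voxel has thickness exactly one voxel spacing, and
  a radius-r cylinder's centerline reads r to within half a voxel. Reported
  diameters are 2× thickness: the published definition measures
  centerline-to-boundary distance (a radius), and doubling it is our
  documented reading of the reported "diameters".
* `aggregateVesselFeatures()`: mean diameter over centerline voxels per
  artery segment (11) and per territory (6), vessel-voxel density per
  territory (6), and the whole-head mean diameter (1) — 24 features, in a
  fixed schema order. Empty regions yield 0 with a warning rather than NA,
  so feature matrices stay complete. Density is defined as the vessel-mask
  voxel fraction of the territory; the emulated protocol does not define
  "density" operationally.

# The predictors

**MLPs** (223 T1 features; 24 artery features + total brain volume):
ReLU hidden layers from the published candidate grids — T1: (256),
(256,128), (256,128,64), (256,128,64,32); TOF: (32), (16,32), (8,16,32),
(4,8,16,32) — with the best-on-average variants (two layers T1, three
layers TOF) as defaults. Inputs are z-scored with statistics fitted on the
training fold (the published learning rate of 0.1 is only plausible with
scaled inputs; activations and initialization are unpublished, so we use
ReLU and He initialization). Training: Adam, MSE, batch 200, 1000 epochs
in the paper-faithful profile.

**CNNs**: the simple fully convolutional architecture for volumetric age
regression — four blocks of (3×3×3 convolution, batch normalization, 2×2×2
max pooling, ReLU) with 32/64/128/256 filters, a (1×1×1, 64-filter,
batch-norm, ReLU) block, then global average pooling (the pool extent is
unpublished; global is the natural choice once the grid has collapsed to
3³ or smaller), dropout 0.5, and a linear dense output. Adam, MSE,
learning rate 0.001, batch 8, 200 epochs in the paper-faithful profile.
Augmentation applies rotations of ±5° and integer translations of ±10
voxels to a random half of each batch, trilinear, out-of-field filled with
the volume median (the phantom background). Convolution, pooling, batch
normalization and resampling run in compiled code; there is no usable deep
learning framework in a plain R stack, and these five kernels are all the
architecture needs.

Two training details are deliberate design choices. First, the dense
output bias is initialized at the mean training age (both families): with
Adam, parameters move at most ≈ lr per step, so an output starting near 0
would spend its entire short schedule traveling to the 50-year operating
point instead of learning. Second, batch-norm running statistics are
bias-corrected exponential moving averages, so inference is well-defined
even after few updates. Checkpointing follows the published protocol:
validation loss is evaluated every epoch and the minimum-loss weights are
returned, never the final epoch.

# Cross-validation, fusion, bias correction, associations

`planFolds()` sorts subjects into 10 age-quantile bins (the bin definition
is unpublished) and deals each bin round-robin into 5 test folds; each
fold's validation set — round(0.15 · n) subjects, which reproduces the
published 249 at n = 1658 — is drawn age-stratified from that fold's
training portion by largest-remainder allocation. The null model predicts
the training-mean age.

`fitStack()` regresses chronological age on the individual models'
*validation* predictions (OLS with intercept; whether the published stack
had one is unstated, so a flag can disable it), per fold, and applies the
fold's weights to its test set — fold-wise rather than pooled to avoid
leakage. Normalized shares divide coefficients by their sum, which is the
convention that reproduces a negative printed share for a harmful model.
Rank-deficient prediction sets fall back to the minimum-norm pseudo-inverse
with a warning. Absolute errors of competing models are compared with
two-sided Wilcoxon signed-rank tests on test subjects pooled across folds
(zero differences dropped; exact distribution for ≤ 25 untied pairs, normal
approximation with tie correction otherwise).

Age-bias correction follows the standard two-step linear scheme: on each
fold's validation set, fit `predicted = α · age + β`; on the test set,
apply `corrected = predicted + [age − (α · age + β)]`. On the fitting set
this leaves the corrected gap with exactly zero mean and zero age
correlation (OLS residual identities, asserted to 1e-10 in the tests). The
BAG is the corrected prediction minus chronological age, computed only for
test subjects never used in training or bias fitting.

`associateBAG()` fits `BAG = β1·age + β2·sex + β3·z(factor)` (plus
intercept; sex coded 0 female / 1 male; ordinal factors entered as
standardized ordinals, matching their single-coefficient treatment) and
reports the two-sided p-value for β3. `fdrCorrect()` applies
Benjamini-Hochberg over the full family of model × factor tests (the
family definition is unpublished; 4 × 5 = 20 jointly is the conservative
reading). Only β3 is FDR-corrected.

The sign convention for the age-related bias is
`bias_r = cor(predicted − age, age)`; under it the null model scores −1,
although comparable published tables print 1 — we report the signed value.
A perfectly calibrated model has a zero-variance gap, for which `bias_r`
is reported as 0 by convention; zero-variance predictions make the Pearson
correlation undefined and are reported as NaN with a warning.

# Profiles, problem sizes and numerical choices

`experimentConfig("paper")` carries the published protocol (n = 1658,
1000/200 epochs, full-resolution inputs). `experimentConfig("desk")` is
the profile the tests and the acceptance script actually run, sized for a
single CPU: 400 subjects, 48³ phantoms, CNN inputs block-averaged to 16³,
MLPs at 250 epochs with learning rate 0.01, CNNs at 3 epochs with
translations of ±3 voxels (scaled to the reduced grid). These sizes are
the package's own choice of a compact but statistically meaningful
experiment: large enough that every individual model clearly beats the
null and the stacked model's ordering is stable, small enough to run
routinely. One master seed fans out to every stage through a fixed
splitting scheme, making runs bit-reproducible; `outDir`/`resume` persist
intermediates (cohort, features, fold plan, predictions) so downstream
stages can be recomputed without retraining.

Degenerate inputs are handled explicitly rather than avoided: empty vessel
masks raise an error naming the threshold; radius clamping warns; empty
atlas regions aggregate to 0 with a warning; collinear stacks warn and use
the pseudo-inverse; all-zero error differences give p = 1 with a warning.

# What passing tests do and do not show

The synthetic generator emulates *structure*, not appearance: monotone
atrophy and artery thinning with known effect sizes, demographically
realistic marginals, a hidden biological-age construct with risk-factor
loadings. It does not emulate scanner physics, registration error,
segmentation failure, site effects, or the heavy-tailed biology of real
cohorts. Passing the suite therefore shows that the pipeline's *methods*
are implemented correctly (exact oracles, parameter recovery, OLS
identities, enumeration-exact tests) and that the full experiment behaves
the way the emulated study reports — individual models beat the null,
fusion helps, bias correction removes the age trend, injected associations
are recovered at calibrated error rates. It does not certify accuracy
numbers on real MRI. Known limitations: threshold segmentation stands in
for level-set vessel segmentation; no image registration (the atlas is
already in phantom space); saliency covers SmoothGrad only; and the desk
profile's few-epoch CNNs rely on the calibrated output bias rather than a
converged training run.
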
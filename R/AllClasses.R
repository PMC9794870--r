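## S4 containers for the simulation and analysis pipeline.

#' Cohort of synthetic subjects
#'
#' Per-subject chronological age, sex, and five cardiovascular risk factors,
#' together with the ground-truth generating parameters when produced by
#' [generateCohort()].
#'
#' @slot subjects data.frame with columns `subject_id`, `age` (years),
#'   `sex` (0 female, 1 male), `bp` (mmHg), `bmi` (kg/m^2), `whr`,
#'   `smoking` (ordinal 0-4), `alcohol` (ordinal 0-3).
#' @slot groundTruth list of generating parameters (round-trips through YAML).
#' @export
setClass("Cohort",
  representation(subjects = "data.frame", groundTruth = "list"),
  prototype(subjects = data.frame(), groundTruth = list())
)

setValidity("Cohort", function(object) {
  df <- object@subjects
  need <- c("subject_id", "age", "sex", "bp", "bmi", "whr", "smoking", "alcohol")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (anyNA(df[need])) return("missing values are not allowed")
  if (nrow(df) > 0) {
    if (any(df$age < 21 | df$age > 81)) return("ages must lie in [21, 81]")
    if (!all(df$sex %in% 0:1)) return("sex must be coded 0/1")
    if (!all(df$smoking %in% 0:4)) return("smoking must be an ordinal code 0-4")
    if (!all(df$alcohol %in% 0:3)) return("alcohol must be an ordinal code 0-3")
    if (anyDuplicated(df$subject_id)) return("duplicated subject ids")
  }
  TRUE
})

#' Subject x feature table
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `features` assay (features x subjects) with subject covariates in
#' `colData`. The T1 morphometry schema has exactly 223 features; the vessel
#' schema has 24 artery features plus total brain volume.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("a 'features' assay is required")
  m <- SummarizedExperiment::assay(object, "features")
  if (!all(is.finite(m))) return("feature values must be finite")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("features must have unique names")
  TRUE
})

#' 3D image volume with voxel spacing
#'
#' @slot voxels numeric 3D array (x fastest, R column-major order).
#' @slot spacing voxel edge lengths in mm, one per axis.
#' @slot modality `"t1"` or `"tof"`.
#' @export
setClass("BrainVolume",
  representation(voxels = "array", spacing = "numeric", modality = "character")
)

setValidity("BrainVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3) return("voxels must be a 3D array")
  if (any(d < 16)) return("all dimensions must be >= 16")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be three positive values")
  if (!object@modality %in% c("t1", "tof"))
    return("modality must be 't1' or 'tof'")
  TRUE
})

#' Atlas of flow territories and artery-segment regions
#'
#' Deterministic geometric partition of a phantom head: six cerebral blood
#' flow territories (MCA/PCA/ACA, left/right) tiling the brain mask, and
#' eleven artery-segment regions placed as tubes around piecewise-linear
#' centerline paths. Lateralized segments lie inside a single territory;
#' BA, ACA-A1 and ACA-A2 run along the midline.
#'
#' @slot territories integer 3D array, 0 = outside, 1..6 territory labels.
#' @slot segments integer 3D array, 0 = none, 1..11 artery-segment labels.
#' @slot territoryNames character(6) naming territory labels in order.
#' @slot segmentNames character(11) naming segment labels in order.
#' @slot spacing voxel spacing (mm).
#' @slot brainMask logical 3D array.
#' @slot paths list of per-segment centerline polylines (voxel coordinates).
#' @slot segmentDistance list of per-segment distance-to-path fields (voxels),
#'   reused when drawing synthetic vessels.
#' @export
setClass("ROIAtlas",
  representation(
    territories = "array", segments = "array",
    territoryNames = "character", segmentNames = "character",
    spacing = "numeric", brainMask = "array", paths = "list",
    segmentDistance = "list"
  )
)

setValidity("ROIAtlas", function(object) {
  if (!identical(dim(object@territories), dim(object@segments)))
    return("territory and segment grids must match")
  if (length(object@territoryNames) != max(object@territories))
    return("territoryNames must name every territory label")
  if (length(object@segmentNames) != max(object@segments))
    return("segmentNames must name every segment label")
  TRUE
})

#' Binary vessel segmentation mask
#'
#' @slot mask logical 3D array on the TOF grid.
#' @slot spacing voxel spacing (mm).
#' @export
setClass("VesselMask",
  representation(mask = "array", spacing = "numeric")
)

setValidity("VesselMask", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3)
    return("mask must be a logical 3D array")
  TRUE
})

#' Vessel centerline with per-voxel thickness
#'
#' One-voxel-wide skeleton of a vessel mask. `thickness` holds the distance
#' (mm) from each centerline voxel to the nearest background voxel center;
#' reported diameters are twice this value.
#'
#' @slot voxels integer matrix (n x 3) of 1-based voxel coordinates.
#' @slot thickness numeric vector (mm), `NA` until [computeThickness()] runs.
#' @slot dim grid dimensions of the originating mask.
#' @slot spacing voxel spacing (mm).
#' @export
setClass("Centerline",
  representation(voxels = "matrix", thickness = "numeric",
                 dim = "integer", spacing = "numeric")
)

setValidity("Centerline", function(object) {
  if (ncol(object@voxels) != 3) return("voxels must have three columns")
  if (length(object@thickness) != nrow(object@voxels))
    return("one thickness value per centerline voxel is required")
  ok <- !is.na(object@thickness)
  if (any(object@thickness[ok] <= 0)) return("thickness must be positive")
  TRUE
})

#' Age-stratified cross-validation fold plan
#'
#' @slot subjectIds character vector of subject ids.
#' @slot testFold integer test-fold assignment per subject (1..k); the test
#'   sets partition the cohort.
#' @slot valIds list of k character vectors: validation subjects per fold,
#'   drawn age-stratified from that fold's training portion.
#' @slot k number of folds.
#' @export
setClass("FoldPlan",
  representation(subjectIds = "character", testFold = "integer",
                 valIds = "list", k = "integer")
)

setValidity("FoldPlan", function(object) {
  if (length(object@testFold) != length(object@subjectIds))
    return("one test fold per subject is required")
  if (!all(object@testFold %in% seq_len(object@k)))
    return("test folds out of range")
  if (length(object@valIds) != object@k)
    return("valIds must have one entry per fold")
  for (f in seq_len(object@k)) {
    test <- object@subjectIds[object@testFold == f]
    if (length(intersect(object@valIds[[f]], test)) > 0)
      return("validation subjects must not appear in the same fold's test set")
  }
  TRUE
})

#' Predictions of one or more age models
#'
#' Long-format container: one row per (subject, model, fold, split).
#'
#' @slot records data.frame with columns `subject_id`, `model`, `fold`,
#'   `split` (`"val"` or `"test"`), `age`, `predicted`, and optionally
#'   `corrected` after age-bias correction.
#' @export
setClass("PredictionSet", representation(records = "data.frame"))

setValidity("PredictionSet", function(object) {
  need <- c("subject_id", "model", "fold", "split", "age", "predicted")
  if (!all(need %in% names(object@records)))
    return(paste("missing columns:", paste(setdiff(need, names(object@records)), collapse = ", ")))
  TRUE
})

#' Multilayer perceptron age regressor
#'
#' Fully connected network with ReLU hidden activations and a single linear
#' output, trained with Adam on mean squared error. Inputs are z-scored with
#' statistics fitted on the training fold.
#'
#' @slot spec list: `hidden` layer sizes, `inputNames`.
#' @slot params list of weight matrices/bias vectors.
#' @slot norm list: feature `center` and `scale` fitted on training data.
#' @slot history data.frame of per-epoch train/validation losses.
#' @slot trained logical.
#' @export
setClass("MLPModel",
  representation(spec = "list", params = "list", norm = "list",
                 history = "data.frame", trained = "logical"),
  prototype(trained = FALSE)
)

#' 3D convolutional age regressor
#'
#' Four blocks of (3x3x3 conv, batch norm, 2x2x2 max pool, ReLU) with 32,
#' 64, 128 and 256 filters, a fifth block of (1x1x1 conv with 64 filters,
#' batch norm, ReLU), and a sixth block of global average pooling, dropout
#' (rate 0.5) and a linear dense output.
#'
#' @slot spec list: `inputDim`, `filters`, `dropout`.
#' @slot params list of layer parameters (conv weights, batch-norm
#'   gamma/beta and running statistics, dense weights).
#' @slot history data.frame of per-epoch losses.
#' @slot trained logical.
#' @export
setClass("CNNModel",
  representation(spec = "list", params = "list",
                 history = "data.frame", trained = "logical"),
  prototype(trained = FALSE)
)

#' Stacked linear combination of model predictions
#'
#' @slot models character: input model ids, in fitting order.
#' @slot intercept numeric.
#' @slot coefficients named numeric, one per input model.
#' @slot shares coefficients divided by their sum (the normalized weights).
#' @slot fold integer fold id.
#' @export
setClass("StackWeights",
  representation(models = "character", intercept = "numeric",
                 coefficients = "numeric", shares = "numeric", fold = "integer")
)

#' Age-bias regression parameters
#'
#' Slope and intercept of the predicted-on-chronological age regression,
#' fitted on validation subjects only.
#'
#' @slot alpha slope.
#' @slot beta intercept.
#' @slot model model id.
#' @slot fold fold id.
#' @export
setClass("BiasParams",
  representation(alpha = "numeric", beta = "numeric",
                 model = "character", fold = "integer")
)

#' Input-importance map
#'
#' @slot values nonnegative importance, same shape as the model input
#'   (named vector for MLPs, 3D array for CNNs).
#' @slot model model id.
#' @slot params list: `nSamples`, `noiseSd`, `seed`.
#' @export
setClass("SaliencyMap",
  representation(values = "ANY", model = "character", params = "list")
)

## ---------------------------------------------------------------------------
## show methods

setMethod("show", "Cohort", function(object) {
  df <- object@subjects
  cat("Cohort with", nrow(df), "subjects\n")
  if (nrow(df) > 0) {
    cat(sprintf("  age: %.1f (sd %.1f), range [%.1f, %.1f]\n",
                mean(df$age), sd(df$age), min(df$age), max(df$age)))
    cat(sprintf("  sex: %d female / %d male\n", sum(df$sex == 0), sum(df$sex == 1)))
  }
})

setMethod("show", "BrainVolume", function(object) {
  cat(sprintf("BrainVolume [%s]: %s voxels, spacing %s mm\n", object@modality,
              paste(dim(object@voxels), collapse = "x"),
              paste(object@spacing, collapse = "x")))
})

setMethod("show", "ROIAtlas", function(object) {
  cat(sprintf("ROIAtlas: %s grid, %d territories, %d artery segments\n",
              paste(dim(object@territories), collapse = "x"),
              length(object@territoryNames), length(object@segmentNames)))
})

setMethod("show", "VesselMask", function(object) {
  cat(sprintf("VesselMask: %s grid, %d foreground voxels\n",
              paste(dim(object@mask), collapse = "x"), sum(object@mask)))
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d voxels%s\n", nrow(object@voxels),
              if (all(is.na(object@thickness))) "" else
                sprintf(", mean thickness %.2f mm", mean(object@thickness))))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d subjects, %d folds, validation sizes %s\n",
              length(object@subjectIds), object@k,
              paste(vapply(object@valIds, length, 1L), collapse = "/")))
})

setMethod("show", "PredictionSet", function(object) {
  r <- object@records
  cat(sprintf("PredictionSet: %d records, models: %s\n", nrow(r),
              paste(unique(r$model), collapse = ", ")))
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf("MLPModel: %d -> %s -> 1%s\n", length(object@spec$inputNames),
              paste(object@spec$hidden, collapse = " -> "),
              if (object@trained) " (trained)" else ""))
})

setMethod("show", "CNNModel", function(object) {
  cat(sprintf("CNNModel: input %s, filters %s%s\n",
              paste(object@spec$inputDim, collapse = "x"),
              paste(object@spec$filters, collapse = "/"),
              if (object@trained) " (trained)" else ""))
})

setMethod("show", "StackWeights", function(object) {
  cat(sprintf("StackWeights (fold %d): intercept %.3f\n", object@fold, object@intercept))
  print(round(object@coefficients, 4))
  cat("normalized shares:\n")
  print(round(object@shares, 4))
})

setMethod("show", "BiasParams", function(object) {
  cat(sprintf("BiasParams [%s, fold %d]: alpha %.4f, beta %.3f\n",
              object@model, object@fold, object@alpha, object@beta))
})
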
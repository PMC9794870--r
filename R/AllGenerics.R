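## Generics and accessors shared across the package.

#' Subject identifiers
#' @param x a Cohort, FeatureTable, FoldPlan or PredictionSet
#' @return character vector of subject ids
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Chronological ages (years)
#' @param x a Cohort or FeatureTable
#' @return numeric vector
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' Ground-truth generating parameters of a synthetic object
#' @param x a Cohort or FeatureTable
#' @return list of parameters
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Subjects-by-features numeric matrix
#' @param x a FeatureTable
#' @return numeric matrix, subjects in rows
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Voxel data of a volume-like object
#' @param x a BrainVolume or VesselMask
#' @return 3D array
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Voxel spacing in mm
#' @param x a volume-like object
#' @return numeric(3)
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Train an age prediction model
#'
#' Minimizes mean squared error with Adam, evaluating the validation loss
#' after every epoch and returning the parameters of the epoch with the
#' lowest validation loss (not the final epoch).
#'
#' @param model an untrained [MLPModel-class] or [CNNModel-class]
#' @param x training inputs (feature matrix, or volume array/list)
#' @param y training ages
#' @param valX,valY validation inputs and ages (disjoint subjects)
#' @param config a [trainConfig()] list
#' @return the trained model, with a per-epoch loss `history`
#' @export
setGeneric("trainModel", function(model, x, y, valX, valY, config = trainConfig())
  standardGeneric("trainModel"))

#' Predict ages for new data
#'
#' Deterministic at inference: dropout is disabled and batch normalization
#' uses running statistics.
#'
#' @param model a trained model
#' @param x inputs matching the model's schema
#' @return numeric vector of predicted ages
#' @export
setGeneric("predictAge", function(model, x) standardGeneric("predictAge"))

#' SmoothGrad input importance
#'
#' Averages absolute input gradients over noise-perturbed copies of the
#' input: `mean_i |d output / d input|` at `input + N(0, sd)`, where the
#' noise standard deviation is expressed as a fraction of the input
#' intensity range.
#'
#' @param model a trained model
#' @param input one input (feature vector or volume array)
#' @param nSamples number of perturbed samples (>= 1)
#' @param noiseSd noise level as a fraction of the input range
#' @param seed integer seed for the perturbations
#' @return a [SaliencyMap-class]
#' @export
setGeneric("smoothGrad", function(model, input, nSamples = 25, noiseSd = 0.1,
                                  seed = NULL)
  standardGeneric("smoothGrad"))

## ---------------------------------------------------------------------------
## accessor methods

#' @describeIn subjectIds cohort subject ids
#' @export
setMethod("subjectIds", "Cohort", function(x) x@subjects$subject_id)

#' @describeIn subjectIds feature-table subject ids
#' @export
setMethod("subjectIds", "FeatureTable", function(x) colnames(x))

#' @describeIn subjectIds fold-plan subject ids
#' @export
setMethod("subjectIds", "FoldPlan", function(x) x@subjectIds)

#' @describeIn ages cohort ages
#' @export
setMethod("ages", "Cohort", function(x) x@subjects$age)

#' @describeIn ages ages stored in the feature-table column data
#' @export
setMethod("ages", "FeatureTable", function(x) colData(x)$age)

#' @describeIn groundTruth cohort generating parameters
#' @export
setMethod("groundTruth", "Cohort", function(x) x@groundTruth)

#' @describeIn groundTruth feature-table generating parameters
#' @export
setMethod("groundTruth", "FeatureTable", function(x) metadata(x)$groundTruth)

#' @describeIn featureMatrix subjects x features matrix
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) t(assay(x, "features")))

#' @describeIn voxels volume voxel array
#' @export
setMethod("voxels", "BrainVolume", function(x) x@voxels)

#' @describeIn voxels logical mask array
#' @export
setMethod("voxels", "VesselMask", function(x) x@mask)

#' @describeIn spacing volume spacing
#' @export
setMethod("spacing", "BrainVolume", function(x) x@spacing)

#' @describeIn spacing mask spacing
#' @export
setMethod("spacing", "VesselMask", function(x) x@spacing)

#' @describeIn spacing atlas spacing
#' @export
setMethod("spacing", "ROIAtlas", function(x) x@spacing)

#' Risk-factor columns of a cohort
#'
#' @param x a [Cohort-class]
#' @param factors which factors to return
#' @return data.frame of risk-factor values
#' @export
riskFactors <- function(x, factors = c("bp", "bmi", "whr", "smoking", "alcohol")) {
  stopifnot(is(x, "Cohort"))
  x@subjects[, factors, drop = FALSE]
}

#' Prediction records as a data.frame
#' @param x a [PredictionSet-class]
#' @return data.frame of prediction records
#' @export
predictionRecords <- function(x) {
  stopifnot(is(x, "PredictionSet"))
  x@records
}

#' Test / validation / training subject ids of one fold
#'
#' In fold `fold`, every subject is exactly one of: test (its assigned test
#' fold), validation (age-stratified draw from the training portion), or
#' training.
#'
#' @param plan a [FoldPlan-class]
#' @param fold fold number in `1..k`
#' @return character vector of subject ids
#' @export
testIds <- function(plan, fold) {
  stopifnot(is(plan, "FoldPlan"))
  plan@subjectIds[plan@testFold == fold]
}

#' @rdname testIds
#' @export
valIds <- function(plan, fold) {
  stopifnot(is(plan, "FoldPlan"))
  plan@valIds[[fold]]
}

#' @rdname testIds
#' @export
trainIds <- function(plan, fold) {
  stopifnot(is(plan, "FoldPlan"))
  setdiff(plan@subjectIds[plan@testFold != fold], plan@valIds[[fold]])
}
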
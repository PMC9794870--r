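## SmoothGrad input importance for both model families.

smoothGradCore <- function(gradFun, input, nSamples, noiseSd, seed) {
  if (nSamples < 1) stop("nSamples must be >= 1")
  rng <- diff(range(input))
  sdAbs <- noiseSd * if (rng > 0) rng else 1
  withSeed(seed, {
    acc <- 0
    for (i in seq_len(nSamples)) {
      pert <- if (sdAbs > 0) input + rnorm(length(input), 0, sdAbs) else input
      if (!is.null(dim(input))) dim(pert) <- dim(input)
      acc <- acc + abs(gradFun(pert))
    }
    acc / nSamples
  })
}

#' @describeIn smoothGrad feature-space importance for an MLP: mean
#'   absolute gradient of the predicted age with respect to each input
#'   feature over noise-perturbed copies of the feature vector
#' @export
setMethod("smoothGrad", "MLPModel", function(model, input, nSamples = 25,
                                             noiseSd = 0.1, seed = NULL) {
  if (!model@trained) stop("model is not trained")
  x <- if (is.matrix(input)) input[1, ] else input
  x <- x[model@spec$inputNames]
  if (anyNA(x)) stop("input is missing features")
  vals <- smoothGradCore(function(p) {
    xs <- (p - model@norm$center) / model@norm$scale
    mlpInputGradient(model, matrix(xs, 1))
  }, x, nSamples, noiseSd, seed)
  names(vals) <- model@spec$inputNames
  new("SaliencyMap", values = vals, model = "mlp",
      params = list(nSamples = nSamples, noiseSd = noiseSd, seed = seed))
})

#' @describeIn smoothGrad voxel-space saliency map for a CNN (inference
#'   mode gradients)
#' @export
setMethod("smoothGrad", "CNNModel", function(model, input, nSamples = 25,
                                             noiseSd = 0.1, seed = NULL) {
  if (!model@trained) stop("model is not trained")
  vol <- if (is(input, "BrainVolume")) input@voxels else input
  stopifnot(all(dim(vol) == model@spec$inputDim))
  vals <- smoothGradCore(function(p) cnnInputGradient(model, p),
                         vol, nSamples, noiseSd, seed)
  new("SaliencyMap", values = vals, model = "cnn",
      params = list(nSamples = nSamples, noiseSd = noiseSd, seed = seed))
})

#' Ranked MLP feature importance
#'
#' [smoothGrad()] on the feature vector, sorted by decreasing importance.
#'
#' @param model a trained [MLPModel-class]
#' @param input named feature vector (or single-row matrix)
#' @param nSamples,noiseSd,seed see [smoothGrad()]
#' @return data.frame with `feature` and `importance`, most important first
#' @export
mlpImportance <- function(model, input, nSamples = 25, noiseSd = 0.1,
                          seed = NULL) {
  sm <- smoothGrad(model, input, nSamples = nSamples, noiseSd = noiseSd,
                   seed = seed)
  ord <- order(sm@values, decreasing = TRUE)
  data.frame(feature = names(sm@values)[ord],
             importance = unname(sm@values[ord]),
             stringsAsFactors = FALSE)
}
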
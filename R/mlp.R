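## Multilayer perceptron age regressor in plain matrix arithmetic.

#' Specify an MLP age regressor
#'
#' The architecture grids evaluated for the two feature modalities are
#' (256), (256, 128), (256, 128, 64), (256, 128, 64, 32) for the 223 T1
#' morphometry features and (32), (16, 32), (8, 16, 32), (4, 8, 16, 32) for
#' the 25 artery features; the defaults used elsewhere in the package are
#' the two-hidden-layer T1 and three-hidden-layer TOF variants. Hidden
#' layers use ReLU; the output is a single linear unit.
#'
#' @param inputNames ordered feature names the model consumes
#' @param hidden integer vector of hidden layer sizes (>= 1 layer)
#' @return an untrained [MLPModel-class]
#' @export
#' @examples
#' m <- mlpSpec(t1FeatureSchema(), hidden = c(256, 128))
#' m
mlpSpec <- function(inputNames, hidden = c(256, 128)) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1))
  new("MLPModel", spec = list(inputNames = inputNames, hidden = as.integer(hidden)),
      params = list(), norm = list(), history = data.frame(), trained = FALSE)
}

#' Candidate hidden-layer grids for the two feature modalities
#'
#' @param modality `"t1"` or `"tof"`
#' @return list of hidden-layer size vectors, one to four layers
#' @export
mlpArchitectureGrid <- function(modality = c("t1", "tof")) {
  switch(match.arg(modality),
         t1 = list(256, c(256, 128), c(256, 128, 64), c(256, 128, 64, 32)),
         tof = list(32, c(16, 32), c(8, 16, 32), c(4, 8, 16, 32)))
}

mlpInitParams <- function(nin, hidden, seed) {
  sizes <- c(nin, hidden, 1L)
  withSeed(seed, lapply(seq_len(length(sizes) - 1), function(l) {
    list(W = matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  }))
}

## forward pass on standardized inputs; returns activations for backprop
mlpForward <- function(params, x) {
  L <- length(params)
  acts <- vector("list", L + 1)
  acts[[1]] <- x
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% params[[l]]$W
    z <- sweep(z, 2, params[[l]]$b, "+")
    acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
  }
  acts
}

## gradient of mean((pred - y)^2) over the batch
mlpBackward <- function(params, acts, y) {
  L <- length(params)
  n <- length(y)
  grads <- vector("list", L)
  delta <- 2 * (acts[[L + 1]] - y) / n      # n x 1
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = t(acts[[l]]) %*% delta,
                       b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
    }
  }
  grads
}

mlpCheckInput <- function(model, x) {
  if (is.null(colnames(x)))
    stop("input features must be named")
  missing <- setdiff(model@spec$inputNames, colnames(x))
  if (length(missing))
    stop("input is missing features: ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  x[, model@spec$inputNames, drop = FALSE]
}

#' @describeIn trainModel Train an MLP on a subjects-by-features matrix.
#'   Inputs are z-scored with statistics fitted on the training rows; the
#'   checkpoint with the lowest validation loss is returned.
#' @export
setMethod("trainModel", "MLPModel", function(model, x, y, valX, valY,
                                             config = trainConfig()) {
  x <- mlpCheckInput(model, as.matrix(x))
  valX <- mlpCheckInput(model, as.matrix(valX))
  if (length(intersect(rownames(x), rownames(valX))) > 0)
    stop("training and validation subjects must be disjoint")
  norm <- zscoreFit(x)
  xs <- zscoreApply(x, norm)
  vs <- zscoreApply(valX, norm)
  params <- mlpInitParams(ncol(xs), model@spec$hidden, config$seed)
  ## warm-start the output bias at the mean training age so short schedules
  ## start from a calibrated baseline instead of spending steps traveling there
  params[[length(params)]]$b <- mean(y)
  opt <- adamInit(params)
  n <- nrow(xs)
  best <- list(loss = Inf, params = params)
  hist <- matrix(NA_real_, config$epochs, 2)
  withSeed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batchSize - 1, n)]
        acts <- mlpForward(params, xs[idx, , drop = FALSE])
        pred <- acts[[length(acts)]]
        loss <- mean((pred - y[idx])^2)
        checkFiniteLoss(loss, epoch)
        epochLoss <- epochLoss + loss * length(idx)
        grads <- mlpBackward(params, acts, y[idx])
        st <- adamStep(params, grads, opt, config$lr)
        params <- st$params
        opt <- st$state
      }
      valPred <- mlpForward(params, vs)[[length(params) + 1]]
      valLoss <- mean((valPred - valY)^2)
      checkFiniteLoss(valLoss, epoch)
      hist[epoch, ] <- c(epochLoss / n, valLoss)
      if (valLoss < best$loss) best <- list(loss = valLoss, params = params)
    }
  })
  model@params <- best$params
  model@norm <- norm
  model@history <- data.frame(epoch = seq_len(config$epochs),
                              train_loss = hist[, 1], val_loss = hist[, 2])
  model@trained <- TRUE
  model
})

#' @describeIn predictAge MLP predictions for a feature matrix (columns are
#'   checked against the training schema; missing features are an error)
#' @export
setMethod("predictAge", "MLPModel", function(model, x) {
  if (!model@trained) stop("model is not trained")
  x <- mlpCheckInput(model, as.matrix(x))
  xs <- zscoreApply(x, model@norm)
  pred <- mlpForward(model@params, xs)[[length(model@params) + 1]]
  drop(pred)
})

## d prediction / d raw input for one input row (1 x p), via backprop
## through the z-score standardization
mlpInputGradient <- function(model, xrow) {
  acts <- mlpForward(model@params, xrow)
  L <- length(model@params)
  delta <- matrix(1, 1, 1)
  for (l in rev(seq_len(L))) {
    delta <- delta %*% t(model@params[[l]]$W)
    if (l > 1) delta <- delta * (acts[[l]] > 0)
  }
  drop(delta) / model@norm$scale
}
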
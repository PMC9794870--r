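## 3D convolutional age regressor: four (conv 3x3x3, batch norm, max pool
## 2x2x2, ReLU) blocks with 32/64/128/256 filters, a 1x1x1 conv block with
## 64 filters, then global average pooling, dropout 0.5 and a linear dense
## output.  Convolution and pooling run in compiled code; batch norm,
## activations and the optimizer live here.

#' Specify the 3D CNN age regressor
#'
#' @param inputDim input grid size, integer(3); each of the four pooling
#'   stages halves it (floor), and every stage must keep at least one voxel,
#'   so the minimum input is 16 per axis
#' @param filters filter counts of the four conv blocks
#' @param dropout dropout rate of the final block
#' @return an untrained [CNNModel-class]
#' @export
#' @examples
#' cnnSpec(c(48, 48, 48))
cnnSpec <- function(inputDim, filters = c(32, 64, 128, 256), dropout = 0.5) {
  inputDim <- as.integer(rep(inputDim, length.out = 3))
  d <- inputDim
  for (i in 1:4) {
    d <- d %/% 2L
    if (any(d < 1L))
      stop("input too small for 4 pooling stages: minimum grid is 16 voxels per axis")
  }
  stopifnot(length(filters) == 4)
  new("CNNModel",
      spec = list(inputDim = inputDim, filters = as.integer(filters),
                  dropout = dropout),
      params = list(), history = data.frame(), trained = FALSE)
}

cnnInitParams <- function(spec, seed) {
  fl <- spec$filters
  cin <- c(1L, fl[1:3])
  withSeed(seed, {
    weights <- list()
    for (i in 1:4) {
      fan <- 27 * cin[i]
      weights[[paste0("conv", i)]] <- list(
        W = matrix(rnorm(fl[i] * fan, 0, sqrt(2 / fan)), fl[i], fan),
        b = rep(0, fl[i]))
      weights[[paste0("bn", i)]] <- list(gamma = rep(1, fl[i]), beta = rep(0, fl[i]))
    }
    weights$conv5 <- list(W = matrix(rnorm(64 * fl[4], 0, sqrt(2 / fl[4])), 64, fl[4]),
                          b = rep(0, 64))
    weights$bn5 <- list(gamma = rep(1, 64), beta = rep(0, 64))
    weights$dense <- list(W = matrix(rnorm(64, 0, sqrt(1 / 64)), 64, 1), b = 0)
    weights
  })
}

cnnInitRunning <- function(spec) {
  sizes <- c(spec$filters, 64)
  r <- lapply(sizes, function(s) list(mean = rep(0, s), var = rep(0, s), t = 0L))
  names(r) <- paste0("bn", 1:5)
  r
}

## batch norm over (voxels, samples) per channel; x is [V, C, B].
## The heavy arithmetic runs in compiled code; running statistics are
## tracked here as bias-corrected exponential moving averages so short
## training runs still get usable inference statistics.
bnTrain <- function(x, gamma, beta, run, momentum = 0.1, eps = 1e-5) {
  bn <- cpp_bn_train(x, gamma, beta, eps)
  run$mean <- (1 - momentum) * run$mean + momentum * as.vector(bn$mean)
  run$var <- (1 - momentum) * run$var + momentum * as.vector(bn$var)
  run$t <- run$t + 1L
  list(out = bn$out, run = run,
       cache = list(xhat = bn$xhat, invstd = as.vector(bn$invstd),
                    gamma = gamma))
}

bnBackward <- function(dout, cache) {
  bb <- cpp_bn_backward(dout, cache$xhat, cache$invstd, cache$gamma)
  list(dx = bb$dx, dgamma = as.vector(bb$dgamma), dbeta = as.vector(bb$dbeta))
}

bnRunningStats <- function(run, momentum = 0.1, eps = 1e-5) {
  corr <- 1 - (1 - momentum)^max(run$t, 1L)
  list(mean = run$mean / corr, var = run$var / corr + eps)
}

bnInfer <- function(x, gamma, beta, run, momentum = 0.1, eps = 1e-5) {
  rs <- bnRunningStats(run, momentum, eps)
  scale <- gamma / sqrt(rs$var)
  cpp_bn_infer(x, scale, beta - rs$mean * scale)
}

asBatchCube <- function(volumes, idx, inputDim) {
  V <- prod(inputDim)
  B <- length(idx)
  x <- array(0, c(V, 1, B))
  for (j in seq_along(idx)) {
    v <- volumes[[idx[j]]]
    if (is(v, "BrainVolume")) v <- v@voxels
    if (!identical(dim(v), inputDim)) stopifnot(all(dim(v) == inputDim))
    x[, 1, j] <- as.vector(v)
  }
  x
}

## full forward pass; training=TRUE uses batch statistics and dropout
cnnForward <- function(weights, running, spec, x, training = FALSE,
                       dropMask = NULL, keepCache = FALSE) {
  dims <- spec$inputDim
  cache <- list(dims = list(), conv_in = list(), pool = list(), bn = list(),
                relu_in = list())
  for (i in 1:4) {
    cache$dims[[i]] <- dims
    cache$conv_in[[i]] <- x
    cv <- weights[[paste0("conv", i)]]
    y <- cpp_conv3_forward(x, cv$W, cv$b, dims)
    bnw <- weights[[paste0("bn", i)]]
    if (training) {
      bn <- bnTrain(y, bnw$gamma, bnw$beta, running[[paste0("bn", i)]])
      running[[paste0("bn", i)]] <- bn$run
      y <- bn$out
      cache$bn[[i]] <- bn$cache
    } else {
      y <- bnInfer(y, bnw$gamma, bnw$beta, running[[paste0("bn", i)]])
    }
    pl <- cpp_maxpool3_forward(y, dims)
    cache$pool[[i]] <- pl$idx
    cache$poolVin <- c(cache$poolVin, prod(dims))
    dims <- pl$dim
    cache$relu_in[[i]] <- pl$y
    x <- cpp_relu(pl$y)
  }
  cache$dims[[5]] <- dims
  cache$conv_in[[5]] <- x
  ## block 5: 1x1x1 conv as a per-sample matrix product
  B <- dim(x)[3]
  V5 <- dim(x)[1]
  C4 <- dim(x)[2]
  y5 <- array(0, c(V5, 64, B))
  for (s in seq_len(B))
    y5[, , s] <- matrix(x[, , s], V5, C4) %*% t(weights$conv5$W)
  y5 <- sweep(y5, 2, weights$conv5$b, "+")
  if (training) {
    bn <- bnTrain(y5, weights$bn5$gamma, weights$bn5$beta, running$bn5)
    running$bn5 <- bn$run
    y5 <- bn$out
    cache$bn[[5]] <- bn$cache
  } else {
    y5 <- bnInfer(y5, weights$bn5$gamma, weights$bn5$beta, running$bn5)
  }
  cache$relu_in[[5]] <- y5
  a5 <- cpp_relu(y5)
  cache$a5 <- a5
  g <- colMeans(a5, dims = 1)                # 64 x B global average pool
  if (is.null(dim(g))) g <- matrix(g, 64, 1)
  if (training && !is.null(dropMask)) {
    g <- g * dropMask / (1 - spec$dropout)
  }
  cache$g <- g
  pred <- drop(t(g) %*% weights$dense$W + weights$dense$b)
  list(pred = pred, cache = if (keepCache) cache else NULL, running = running)
}

cnnBackward <- function(weights, spec, cache, dpred, dropMask = NULL,
                        needInputGrad = FALSE, inference = FALSE,
                        running = NULL) {
  B <- length(dpred)
  grads <- list()
  g <- cache$g
  grads$dense <- list(W = g %*% matrix(dpred, B, 1), b = sum(dpred))
  dg <- weights$dense$W %*% matrix(dpred, 1, B)   # 64 x B
  if (!is.null(dropMask)) dg <- dg * dropMask / (1 - spec$dropout)
  V5 <- dim(cache$a5)[1]
  da5 <- array(0, c(V5, 64, B))
  for (s in seq_len(B)) da5[, , s] <- matrix(dg[, s] / V5, V5, 64, byrow = TRUE)
  dy5 <- cpp_relu_backward(da5, cache$relu_in[[5]])
  if (inference) {
    rs <- bnRunningStats(running$bn5)
    dy5 <- sweep(dy5, 2, weights$bn5$gamma / sqrt(rs$var), "*")
    grads$bn5 <- list(gamma = rep(0, 64), beta = rep(0, 64))
  } else {
    bb <- bnBackward(dy5, cache$bn[[5]])
    dy5 <- bb$dx
    grads$bn5 <- list(gamma = bb$dgamma, beta = bb$dbeta)
  }
  x5 <- cache$conv_in[[5]]
  dW5 <- matrix(0, 64, spec$filters[4])
  dx <- array(0, dim(x5))
  for (s in seq_len(B)) {
    dy5s <- matrix(dy5[, , s], V5, 64)
    dW5 <- dW5 + t(dy5s) %*% matrix(x5[, , s], V5, spec$filters[4])
    dx[, , s] <- dy5s %*% weights$conv5$W
  }
  grads$conv5 <- list(W = dW5, b = apply(dy5, 2, sum))
  for (i in 4:1) {
    dx <- cpp_relu_backward(dx, cache$relu_in[[i]])
    dx <- cpp_maxpool3_backward(dx, cache$pool[[i]], cache$poolVin[i])
    if (inference) {
      rs <- bnRunningStats(running[[paste0("bn", i)]])
      dx <- sweep(dx, 2, weights[[paste0("bn", i)]]$gamma / sqrt(rs$var), "*")
      grads[[paste0("bn", i)]] <- list(gamma = 0 * rs$mean, beta = 0 * rs$mean)
    } else {
      bb <- bnBackward(dx, cache$bn[[i]])
      dx <- bb$dx
      grads[[paste0("bn", i)]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    }
    cb <- cpp_conv3_backward(cache$conv_in[[i]], weights[[paste0("conv", i)]]$W,
                             dx, cache$dims[[i]], i > 1 || needInputGrad)
    grads[[paste0("conv", i)]] <- list(W = cb$dW, b = as.vector(cb$db))
    if (i > 1 || needInputGrad) dx <- cb$dx
  }
  list(grads = grads[names(weights)], dinput = dx)
}

#' @describeIn trainModel Train the 3D CNN on a list of volumes (arrays or
#'   [BrainVolume-class] objects). Each batch applies random rotation and
#'   translation augmentation to `augmentFraction` of its samples; the
#'   checkpoint with the lowest validation loss is returned. The dense
#'   output bias is initialized to the mean training age so short training
#'   schedules start from a calibrated baseline.
#' @export
setMethod("trainModel", "CNNModel", function(model, x, y, valX, valY,
                                             config = cnnTrainConfig()) {
  spec <- model@spec
  weights <- cnnInitParams(spec, config$seed)
  weights$dense$b <- mean(y)
  running <- cnnInitRunning(spec)
  opt <- adamInit(weights)
  n <- length(x)
  stopifnot(n == length(y))
  best <- list(loss = Inf, weights = weights, running = running)
  hist <- matrix(NA_real_, config$epochs, 2)
  withSeed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batchSize - 1, n)]
        xb <- asBatchCube(x, idx, spec$inputDim)
        if (config$augmentFraction > 0) {
          aug <- runif(length(idx)) < config$augmentFraction
          for (j in which(aug)) {
            xb[, 1, j] <- as.vector(applyAugmentation(
              array(xb[, 1, j], spec$inputDim),
              rotation = runif(3, -config$rotationDeg, config$rotationDeg),
              translation = sample(-config$translationVox:config$translationVox, 3,
                                   replace = TRUE)))
          }
        }
        dropMask <- matrix(runif(64 * length(idx)) >= spec$dropout, 64, length(idx))
        fw <- cnnForward(weights, running, spec, xb, training = TRUE,
                         dropMask = dropMask, keepCache = TRUE)
        running <- fw$running
        loss <- mean((fw$pred - y[idx])^2)
        checkFiniteLoss(loss, epoch)
        epochLoss <- epochLoss + loss * length(idx)
        bw <- cnnBackward(weights, spec, fw$cache,
                          2 * (fw$pred - y[idx]) / length(idx),
                          dropMask = dropMask)
        st <- adamStep(weights, bw$grads, opt, config$lr)
        weights <- st$params
        opt <- st$state
      }
      valPred <- cnnPredictBatched(weights, running, spec, valX)
      valLoss <- mean((valPred - valY)^2)
      checkFiniteLoss(valLoss, epoch)
      hist[epoch, ] <- c(epochLoss / n, valLoss)
      if (valLoss < best$loss)
        best <- list(loss = valLoss, weights = weights, running = running)
    }
  })
  model@params <- list(weights = best$weights, running = best$running)
  model@history <- data.frame(epoch = seq_len(config$epochs),
                              train_loss = hist[, 1], val_loss = hist[, 2])
  model@trained <- TRUE
  model
})

cnnPredictBatched <- function(weights, running, spec, volumes, chunk = 16) {
  n <- length(volumes)
  pred <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    xb <- asBatchCube(volumes, idx, spec$inputDim)
    pred[idx] <- cnnForward(weights, running, spec, xb)$pred
  }
  pred
}

#' @describeIn predictAge CNN predictions for a list of volumes (inference
#'   mode: running batch-norm statistics, no dropout, no augmentation)
#' @export
setMethod("predictAge", "CNNModel", function(model, x) {
  if (!model@trained) stop("model is not trained")
  if (is(x, "BrainVolume") || (is.array(x) && length(dim(x)) == 3)) x <- list(x)
  first <- if (is(x[[1]], "BrainVolume")) x[[1]]@voxels else x[[1]]
  if (!all(dim(first) == model@spec$inputDim))
    stop(sprintf("volume grid %s does not match the model input %s",
                 paste(dim(first), collapse = "x"),
                 paste(model@spec$inputDim, collapse = "x")))
  cnnPredictBatched(model@params$weights, model@params$running, model@spec, x)
})

## d prediction / d input volume for one volume, in inference mode
cnnInputGradient <- function(model, vol) {
  spec <- model@spec
  xb <- asBatchCube(list(vol), 1L, spec$inputDim)
  fw <- cnnForward(model@params$weights, model@params$running, spec, xb,
                   training = FALSE, keepCache = TRUE)
  ## inference forward caches lack batch-norm caches; rebuild minimal ones
  bw <- cnnBackward(model@params$weights, spec, fw$cache, dpred = 1,
                    needInputGrad = TRUE, inference = TRUE,
                    running = model@params$running)
  array(bw$dinput[, 1, 1], spec$inputDim)
}
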
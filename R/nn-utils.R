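## Shared optimizer machinery for the hand-written networks.

#' Training configuration
#'
#' Hyperparameters for [trainModel()]. Defaults follow the MLP protocol
#' (Adam, learning rate 0.1, batch size 200, 1000 epochs); CNN training
#' uses learning rate 0.001, batch size 8, 200 epochs with augmentation
#' applied to half of each batch.
#'
#' @param optimizer only `"adam"` is implemented
#' @param lr learning rate
#' @param batchSize minibatch size
#' @param epochs training epochs
#' @param augmentFraction fraction of each batch receiving random
#'   rotation/translation augmentation (CNN only)
#' @param rotationDeg rotation range, degrees per axis
#' @param translationVox translation range, voxels per axis
#' @param seed integer seed controlling shuffling, dropout and augmentation
#' @return a list of class `trainConfig`
#' @export
trainConfig <- function(optimizer = "adam", lr = 0.1, batchSize = 200,
                        epochs = 1000, augmentFraction = 0.5,
                        rotationDeg = 5, translationVox = 10, seed = 1) {
  stopifnot(optimizer == "adam", lr > 0, batchSize >= 1, epochs >= 1,
            augmentFraction >= 0, augmentFraction <= 1)
  structure(list(optimizer = optimizer, lr = lr, batchSize = batchSize,
                 epochs = epochs, augmentFraction = augmentFraction,
                 rotationDeg = rotationDeg, translationVox = translationVox,
                 seed = seed), class = "trainConfig")
}

#' @rdname trainConfig
#' @export
cnnTrainConfig <- function(lr = 0.001, batchSize = 8, epochs = 200, ...) {
  trainConfig(lr = lr, batchSize = batchSize, epochs = epochs, ...)
}

adamInit <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0)
}

## One Adam step over a nested parameter/gradient list (in-place semantics
## via returned copies).  beta1/beta2/eps are the standard defaults.
adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

checkFiniteLoss <- function(loss, epoch) {
  if (!is.finite(loss))
    stop(sprintf("non-finite training loss (%.4g) at epoch %d; reduce the learning rate",
                 loss, epoch))
}
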
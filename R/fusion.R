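## Stacked linear fusion of individual model predictions, and paired
## comparison of absolute errors.

#' Fit a linear stack on validation predictions
#'
#' Ordinary least squares of chronological age on the individual models'
#' validation predictions (with intercept by default), fitted per fold.
#' Normalized shares are the coefficients divided by their sum, the
#' convention behind reported modality weights. Collinear prediction sets
#' (rank-deficient design) produce a warning and the minimum-norm
#' pseudo-inverse solution.
#'
#' @param valPredictions named list of numeric vectors, one per model, all
#'   over the same validation subjects
#' @param valAges chronological ages of those subjects
#' @param intercept include an intercept (default TRUE)
#' @param fold fold id for bookkeeping
#' @return a [StackWeights-class]
#' @export
#' @examples
#' ages <- 30:59
#' fitStack(list(a = ages + rnorm(30), b = ages + rnorm(30)), ages)
fitStack <- function(valPredictions, valAges, intercept = TRUE, fold = 1L) {
  stopifnot(is.list(valPredictions), length(valPredictions) >= 1)
  if (is.null(names(valPredictions)) || any(names(valPredictions) == ""))
    stop("valPredictions must be a named list")
  lens <- vapply(valPredictions, length, 1L)
  if (any(lens != length(valAges)))
    stop("all models must predict the same validation subjects")
  X <- do.call(cbind, valPredictions)
  D <- if (intercept) cbind(1, X) else X
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    warning("collinear model predictions; using the pseudo-inverse solution")
    sv <- svd(D)
    keep <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% valAges) / sv$d[keep])
    beta <- drop(beta)
  } else {
    beta <- drop(qr.coef(qrd, valAges))
  }
  if (intercept) {
    b0 <- beta[1]
    coefs <- beta[-1]
  } else {
    b0 <- 0
    coefs <- beta
  }
  names(coefs) <- names(valPredictions)
  new("StackWeights", models = names(valPredictions), intercept = unname(b0),
      coefficients = coefs, shares = coefs / sum(coefs), fold = as.integer(fold))
}

#' Apply stack weights to test predictions
#'
#' @param weights a [StackWeights-class]
#' @param testPredictions named list of numeric vectors with exactly the
#'   model set (and order) the stack was fitted on
#' @return numeric vector of combined predictions
#' @export
applyStack <- function(weights, testPredictions) {
  stopifnot(is(weights, "StackWeights"))
  if (!identical(names(testPredictions), weights@models))
    stop("model set/order mismatch: stack was fitted on ",
         paste(weights@models, collapse = ", "))
  X <- do.call(cbind, testPredictions)
  drop(weights@intercept + X %*% weights@coefficients)
}

#' Paired Wilcoxon signed-rank comparison of absolute errors
#'
#' Two-sided test on the per-subject difference of absolute errors.
#' Zero differences are dropped; with 25 or fewer informative pairs and no
#' ties the exact signed-rank distribution is used, otherwise the normal
#' approximation with tie correction.
#'
#' @param errorsA,errorsB signed or absolute prediction errors of two
#'   models on the same subjects, in the same order
#' @return list with `p.value`, `statistic`, `n` (informative pairs) and
#'   `method`
#' @export
#' @examples
#' compareAbsErrors(rnorm(30), rnorm(30, 1))
compareAbsErrors <- function(errorsA, errorsB) {
  stopifnot(length(errorsA) == length(errorsB))
  d <- abs(errorsA) - abs(errorsB)
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all absolute-error differences are zero; p = 1")
    return(list(p.value = 1, statistic = NA_real_, n = 0L,
                method = "degenerate"))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 25 && !ties
  wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = FALSE))
  list(p.value = wt$p.value, statistic = unname(wt$statistic),
       n = length(d), method = if (exact) "exact" else "normal approximation")
}
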
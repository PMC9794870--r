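## Age-bias correction, brain age gap, and risk-factor associations.

#' Fit age-bias regression parameters on validation predictions
#'
#' Ordinary least squares of predicted age on chronological age,
#' `predicted = alpha * age + beta`, fitted on validation subjects only
#' (never on subjects used to estimate the correction's targets).
#'
#' @param valAges validation chronological ages (>= 3, nonzero variance)
#' @param valPredictions the model's predictions for those subjects
#' @param model,fold ids for bookkeeping
#' @return a [BiasParams-class]
#' @export
#' @examples
#' a <- runif(50, 25, 75)
#' fitBias(a, 0.6 * a + 18)
fitBias <- function(valAges, valPredictions, model = "model", fold = 1L) {
  if (length(valAges) < 3) stop("at least 3 validation subjects are required")
  if (var(valAges) == 0) stop("validation ages have zero variance")
  fit <- lm(valPredictions ~ valAges)
  new("BiasParams", alpha = unname(coef(fit)[2]), beta = unname(coef(fit)[1]),
      model = model, fold = as.integer(fold))
}

#' Correct predictions for age-related bias
#'
#' Applies `corrected = predicted + [age - (age * alpha + beta)]` with
#' parameters estimated on the validation set. When predictions are an
#' exact line in age the corrected predictions equal the chronological age,
#' and on the fitting set the corrected gap has exactly zero mean and zero
#' correlation with age (the OLS residual identities).
#'
#' @param predictions predicted ages
#' @param age chronological ages
#' @param params a [BiasParams-class]
#' @return numeric vector of corrected predicted ages
#' @export
correctPredictions <- function(predictions, age, params) {
  stopifnot(is(params, "BiasParams"), length(predictions) == length(age))
  predictions + (age - (age * params@alpha + params@beta))
}

#' Brain age gap of corrected predictions
#'
#' @param corrected corrected predicted ages
#' @param age chronological ages
#' @return numeric vector, `corrected - age` (years); positive values mean
#'   an older-looking brain
#' @export
computeBAG <- function(corrected, age) {
  stopifnot(length(corrected) == length(age))
  corrected - age
}

#' Association of the brain age gap with one risk factor
#'
#' Multiple linear regression
#' `BAG = b1 * age + b2 * sex + b3 * z(factor)` (plus intercept), with the
#' risk factor standardized to mean 0 and sd 1 so coefficients are
#' comparable across factors. Returns the three coefficients, their
#' standard errors, and the two-sided p-value for the risk-factor
#' coefficient `b3`.
#'
#' @param bag brain age gap values
#' @param age chronological ages
#' @param sex sex codes (0 female, 1 male)
#' @param factor risk-factor values (nonzero variance)
#' @param factorName,model labels for the output row
#' @return one-row data.frame with `model`, `factor`, `beta1`, `beta2`,
#'   `beta3`, `se1`-`se3`, `p`
#' @export
associateBAG <- function(bag, age, sex, factor, factorName = "factor",
                         model = "model") {
  n <- length(bag)
  stopifnot(length(age) == n, length(sex) == n, length(factor) == n)
  if (sd(factor) == 0) stop("risk factor has zero variance")
  z <- (factor - mean(factor)) / sd(factor)
  fit <- summary(lm(bag ~ age + sex + z))$coefficients
  data.frame(model = model, factor = factorName,
             beta1 = fit["age", 1], beta2 = fit["sex", 1], beta3 = fit["z", 1],
             se1 = fit["age", 2], se2 = fit["sex", 2], se3 = fit["z", 2],
             p = fit["z", 4], stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false discovery rate adjustment over one family of tests (by
#' default all model x risk-factor associations are one family).
#'
#' @param p raw p-values in \[0, 1\]
#' @return adjusted q-values, same length and order
#' @export
#' @examples
#' fdrCorrect(c(0.01, 0.02, 0.03, 0.04))
fdrCorrect <- function(p) {
  if (length(p) == 0) stop("empty p-value family")
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Full association table across models and risk factors
#'
#' Runs [associateBAG()] for every (model, factor) pair and applies
#' [fdrCorrect()] jointly over all resulting p-values (one family).
#'
#' @param bagRecords data.frame with columns `subject_id`, `model`, `bag`
#' @param cohort the [Cohort-class] supplying age, sex and factors
#' @param factors risk-factor column names to test
#' @param alpha significance level on the corrected scale
#' @return data.frame with one row per model and factor, including `q` and
#'   `significant`
#' @export
associationTable <- function(bagRecords, cohort,
                             factors = c("bp", "bmi", "whr", "smoking", "alcohol"),
                             alpha = 0.05) {
  stopifnot(is(cohort, "Cohort"),
            all(c("subject_id", "model", "bag") %in% names(bagRecords)))
  subj <- cohort@subjects
  ix <- match(bagRecords$subject_id, subj$subject_id)
  if (anyNA(ix)) stop("BAG records contain unknown subjects")
  rows <- list()
  for (m in unique(bagRecords$model)) {
    sel <- bagRecords$model == m
    for (f in factors) {
      rows[[paste(m, f)]] <- associateBAG(
        bagRecords$bag[sel], subj$age[ix[sel]], subj$sex[ix[sel]],
        subj[[f]][ix[sel]], factorName = f, model = m)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- fdrCorrect(out$p)
  out$significant <- out$q < alpha
  out
}
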
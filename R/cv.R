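## Age-stratified cross-validation harness, null model and metrics.

#' Plan an age-stratified k-fold cross-validation
#'
#' Subjects are sorted into `nBins` age-quantile bins and assigned to test
#' folds round-robin within each bin, so every fold spans the age range and
#' the test sets partition the cohort. For each fold, a validation set of
#' `round(valFrac * n)` subjects is drawn age-stratified from that fold's
#' training portion (largest-remainder allocation across bins), matching a
#' 15% validation split of 249 subjects at n = 1658.
#'
#' @param cohort a [Cohort-class]
#' @param k number of folds
#' @param valFrac validation fraction of the whole cohort
#' @param nBins number of age-quantile strata
#' @param seed integer seed
#' @return a [FoldPlan-class]
#' @export
#' @examples
#' coh <- generateCohort(200, seed = 1)
#' planFolds(coh, seed = 2)
planFolds <- function(cohort, k = 5, valFrac = 0.15, nBins = 10, seed = NULL) {
  stopifnot(is(cohort, "Cohort"))
  n <- nrow(cohort@subjects)
  if (k > n) stop("more folds than subjects")
  if (n < k * nBins) stop("need at least k * nBins subjects")
  age <- ages(cohort)
  ids <- subjectIds(cohort)
  breaks <- unique(quantile(age, probs = seq(0, 1, length.out = nBins + 1)))
  bin <- cut(age, breaks, include.lowest = TRUE, labels = FALSE)
  withSeed(seed, {
    testFold <- integer(n)
    for (b in unique(bin)) {
      members <- sample(which(bin == b))
      testFold[members] <- rep_len(seq_len(k), length(members))
    }
    valTarget <- round(valFrac * n)
    valIds <- lapply(seq_len(k), function(f) {
      pool <- which(testFold != f)
      poolBins <- split(pool, bin[pool])
      sizes <- vapply(poolBins, length, 1L)
      quota <- floor(valTarget * sizes / sum(sizes))
      rem <- valTarget - sum(quota)
      if (rem > 0) {
        frac <- valTarget * sizes / sum(sizes) - quota
        bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
        quota[bump] <- quota[bump] + 1L
      }
      picks <- unlist(mapply(function(members, q) {
        sample(members, min(q, length(members)))
      }, poolBins, quota, SIMPLIFY = FALSE), use.names = FALSE)
      ids[picks]
    })
    new("FoldPlan", subjectIds = ids, testFold = testFold,
        valIds = valIds, k = as.integer(k))
  })
}

#' Null model: predict the training-set mean age
#'
#' @param trainAges training ages (nonempty)
#' @param testAges test ages
#' @param testIds optional subject ids
#' @param fold fold id for bookkeeping
#' @return a [PredictionSet-class] with model id `"null"`
#' @export
nullModel <- function(trainAges, testAges, testIds = NULL, fold = 1L) {
  if (length(trainAges) == 0) stop("training ages must be nonempty")
  if (is.null(testIds)) testIds <- sprintf("S%05d", seq_along(testAges))
  new("PredictionSet", records = data.frame(
    subject_id = testIds, model = "null", fold = as.integer(fold),
    split = "test", age = testAges, predicted = mean(trainAges),
    stringsAsFactors = FALSE))
}

#' Prediction metrics: MAE, Pearson r, and age-related bias
#'
#' `mae` is the mean absolute error in years; `pearson_r` the correlation
#' between chronological and predicted age; `bias_r` the correlation
#' between the brain age gap (predicted minus chronological) and
#' chronological age, the usual measure of regression-to-the-mean bias.
#' Zero-variance predictions give `pearson_r = NaN` with a warning; a
#' zero-variance gap (e.g. perfect predictions) gives `bias_r = 0` by
#' convention, since no age trend exists in a constant gap.
#'
#' @param age chronological ages (or a [PredictionSet-class])
#' @param predicted predicted ages (ignored when `age` is a PredictionSet)
#' @return data.frame row with `mae`, `pearson_r`, `bias_r`, `n`
#' @export
#' @examples
#' evaluatePredictions(c(30, 50, 70), c(35, 48, 66))
evaluatePredictions <- function(age, predicted = NULL) {
  if (is(age, "PredictionSet")) {
    r <- age@records
    predicted <- if ("corrected" %in% names(r)) r$corrected else r$predicted
    age <- r$age
  }
  stopifnot(length(age) == length(predicted))
  if (length(age) < 3) stop("at least 3 subjects are required")
  gap <- predicted - age
  pr <- if (sd(predicted) == 0) {
    warning("zero-variance predictions: pearson_r is undefined")
    NaN
  } else cor(age, predicted)
  br <- if (sd(gap) == 0) 0 else cor(gap, age)
  data.frame(mae = mean(abs(gap)), pearson_r = pr, bias_r = br,
             n = length(age))
}

#' Per-fold metrics and their cross-fold summary
#'
#' @param predictions a [PredictionSet-class] with a `fold` column
#' @param useCorrected evaluate bias-corrected predictions when present
#' @return list with `byFold` (one metrics row per model and fold) and
#'   `summary` (mean and sd across folds per model)
#' @export
evaluateByFold <- function(predictions, useCorrected = FALSE) {
  r <- predictionRecords(predictions)
  if (useCorrected && !"corrected" %in% names(r))
    stop("no corrected predictions present")
  pred <- if (useCorrected) r$corrected else r$predicted
  byFold <- do.call(rbind, lapply(split(seq_len(nrow(r)),
                                        list(r$model, r$fold), drop = TRUE),
    function(ix) {
      m <- suppressWarnings(evaluatePredictions(r$age[ix], pred[ix]))
      cbind(model = r$model[ix[1]], fold = r$fold[ix[1]], m)
    }))
  rownames(byFold) <- NULL
  agg <- do.call(rbind, lapply(split(byFold, byFold$model), function(d) {
    data.frame(model = d$model[1],
               mae = mean(d$mae), mae_sd = sd(d$mae),
               pearson_r = mean(d$pearson_r), pearson_r_sd = sd(d$pearson_r),
               bias_r = mean(d$bias_r), bias_r_sd = sd(d$bias_r),
               folds = nrow(d))
  }))
  rownames(agg) <- NULL
  list(byFold = byFold, summary = agg)
}

#' Serialize a fold plan as CSV
#'
#' One row per subject and fold with role `test`, `val` or `train`.
#'
#' @param plan a [FoldPlan-class]
#' @param path file path
#' @return `readFoldPlan` returns a [FoldPlan-class]
#' @export
writeFoldPlan <- function(plan, path) {
  rows <- do.call(rbind, lapply(seq_len(plan@k), function(f) {
    role <- rep("train", length(plan@subjectIds))
    role[plan@testFold == f] <- "test"
    role[plan@subjectIds %in% plan@valIds[[f]]] <- "val"
    data.frame(subject_id = plan@subjectIds, fold = f, role = role)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFoldPlan
#' @export
readFoldPlan <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  k <- max(df$fold)
  first <- df[df$fold == 1, ]
  testFold <- integer(nrow(first))
  names(testFold) <- first$subject_id
  for (f in seq_len(k)) {
    d <- df[df$fold == f & df$role == "test", ]
    testFold[d$subject_id] <- f
  }
  valIds <- lapply(seq_len(k), function(f)
    df$subject_id[df$fold == f & df$role == "val"])
  new("FoldPlan", subjectIds = first$subject_id,
      testFold = unname(testFold), valIds = valIds, k = as.integer(k))
}
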
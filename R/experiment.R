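## End-to-end experiment: simulate -> extract -> train -> evaluate -> fuse
## -> bias-correct -> associate, from one config with one seed.

#' Experiment configuration
#'
#' Two named profiles are shipped. `"desk"` is the default used by tests
#' and examples: a 400-subject cohort, 48^3 phantoms, CNN inputs block
#' averaged to 16^3, short training schedules (MLP 250 epochs at learning
#' rate 0.01, CNN 3 epochs at 0.001) sized for a single CPU.
#' `"paper"` mirrors the full published protocol (1,658 subjects, MLP 1000
#' epochs at learning rate 0.1 with batch 200, CNN 200 epochs at 0.001
#' with batch 8, full-resolution inputs, translations of +/- 10 voxels);
#' it is provided for completeness and is not sized for test runs.
#'
#' @param profile `"desk"` or `"paper"`
#' @param n cohort size
#' @param gridSize phantom grid (voxels per axis)
#' @param cnnDownsample block-averaging factor for CNN inputs
#' @param mlpT1Hidden,mlpTofHidden hidden-layer sizes of the two MLPs
#'   (defaults are the best-on-average architectures: two hidden layers for
#'   T1 morphometry, three for the artery features)
#' @param mlpConfig,cnnConfig [trainConfig()] lists
#' @param noiseSdT1,noiseSdTof phantom noise levels
#' @param k,valFrac,nBins cross-validation parameters
#' @param factors risk factors tested for BAG association
#' @return a list of class `experimentConfig`
#' @export
experimentConfig <- function(profile = c("desk", "paper"),
                             n = NULL, gridSize = NULL, cnnDownsample = NULL,
                             mlpT1Hidden = c(256, 128),
                             mlpTofHidden = c(8, 16, 32),
                             mlpConfig = NULL, cnnConfig = NULL,
                             noiseSdT1 = 0.05, noiseSdTof = 0.5,
                             k = 5, valFrac = 0.15, nBins = 10,
                             factors = c("bp", "bmi", "whr", "smoking", "alcohol")) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    n <- n %||% 400
    gridSize <- gridSize %||% 48
    cnnDownsample <- cnnDownsample %||% 3
    mlpConfig <- mlpConfig %||% trainConfig(lr = 0.01, batchSize = 200, epochs = 250)
    cnnConfig <- cnnConfig %||% cnnTrainConfig(epochs = 3, translationVox = 3,
                                               rotationDeg = 5)
  } else {
    n <- n %||% 1658
    gridSize <- gridSize %||% 96
    cnnDownsample <- cnnDownsample %||% 1
    mlpConfig <- mlpConfig %||% trainConfig(lr = 0.1, batchSize = 200, epochs = 1000)
    cnnConfig <- cnnConfig %||% cnnTrainConfig(epochs = 200, translationVox = 10,
                                               rotationDeg = 5)
  }
  structure(list(profile = profile, n = n, gridSize = gridSize,
                 cnnDownsample = cnnDownsample,
                 mlpT1Hidden = mlpT1Hidden, mlpTofHidden = mlpTofHidden,
                 mlpConfig = mlpConfig, cnnConfig = cnnConfig,
                 noiseSdT1 = noiseSdT1, noiseSdTof = noiseSdTof,
                 k = k, valFrac = valFrac, nBins = nBins, factors = factors),
            class = "experimentConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

individualModels <- c("mlp_t1", "mlp_tof", "cnn_t1", "cnn_tof")

modelCombos <- list(
  combined_t1 = c("cnn_t1", "mlp_t1"),
  combined_tof = c("cnn_tof", "mlp_tof"),
  combined_mlp = c("mlp_t1", "mlp_tof"),
  combined_cnn = c("cnn_t1", "cnn_tof"),
  all_combined = c("cnn_t1", "cnn_tof", "mlp_t1", "mlp_tof")
)

modelRowOrder <- c("null", individualModels, names(modelCombos))

#' Run the full multimodal brain-age experiment
#'
#' Simulates a cohort, morphometry and phantom volumes, extracts artery
#' features, trains the four individual predictors under age-stratified
#' k-fold cross-validation, fuses them by stacked linear regression, tests
#' absolute-error differences, applies age-bias correction, computes the
#' brain age gap, and regresses it on cardiovascular risk factors with FDR
#' control. Fully deterministic given `seed`: one global seed is fanned
#' out to every stage.
#'
#' @param config an [experimentConfig()]
#' @param seed integer master seed
#' @param outDir optional directory for intermediates and result tables
#' @param resume reuse predictions found in `outDir` (volumes and models
#'   are regenerated deterministically when absent)
#' @param verbose print stage progress
#' @return list with elements `cohort`, `foldPlan`, `predictions`
#'   (a [PredictionSet-class] of test and validation predictions),
#'   `metrics` (per-fold and summary tables over the 10 model rows),
#'   `stackWeights`, `stackShares`, `wilcoxon`, `biasParams`,
#'   `biasComparison`, `bagRecords`, `associations`, `config`, `seed`
#' @export
runExperiment <- function(config = experimentConfig(), seed = 1,
                          outDir = NULL, resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "experimentConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  withFile <- function(name) if (is.null(outDir)) NULL else file.path(outDir, name)

  ## ---- stage 1: cohort and feature simulation
  say("[1/6] simulating cohort (n = %d)", config$n)
  cohort <- generateCohort(config$n, seed = stageSeed(seed, "cohort"))
  gtM <- morphometryGroundTruth(seed = stageSeed(seed, "morphometry"))
  ftT1 <- generateMorphometry(cohort, gtM, seed = stageSeed(seed, "morphometry", 1))
  xT1 <- featureMatrix(ftT1)
  age <- ages(cohort)
  ids <- subjectIds(cohort)
  n <- config$n

  ## ---- stage 2: phantoms and vessel morphometry
  predPath <- withFile("predictions.csv")
  havePreds <- resume && !is.null(predPath) && file.exists(predPath)
  atlas <- makeRoiAtlas(config$gridSize)
  phGt <- phantomGroundTruth()
  xTof <- NULL
  volT1 <- volTof <- NULL
  if (!havePreds) {
    say("[2/6] generating %d^3 phantoms and extracting artery features", config$gridSize)
    ds <- config$cnnDownsample
    volT1 <- vector("list", n)
    volTof <- vector("list", n)
    vf <- matrix(NA_real_, n, 24, dimnames = list(ids, vesselFeatureSchema(atlas)))
    bioAge <- biologicalAges(cohort)   # phantoms look their biological age
    for (i in seq_len(n)) {
      t1 <- generateBrainVolume(bioAge[i], config$gridSize, phGt,
                                seed = stageSeed(seed, "volumes", i),
                                noiseSd = config$noiseSdT1)
      volT1[[i]] <- downsampleVolume(t1, ds)@voxels
      tof <- generateVesselVolume(bioAge[i], atlas, phGt,
                                  seed = stageSeed(seed, "volumes", i + n),
                                  noiseSd = config$noiseSdTof)
      vf[i, ] <- extractVesselFeatures(tof$volume, atlas)
      v <- tof$volume@voxels
      z <- (v - mean(v)) / sd(v)
      volTof[[i]] <- downsampleVolume(
        new("BrainVolume", voxels = z, spacing = tof$volume@spacing,
            modality = "tof"), ds)@voxels
    }
    xTof <- cbind(vf, TotalBrainVol = xT1[, "TotalBrainVol"])
  }

  ## ---- stage 3: cross-validation plan
  plan <- planFolds(cohort, k = config$k, valFrac = config$valFrac,
                    nBins = config$nBins, seed = stageSeed(seed, "folds"))

  ## ---- stage 4: model training and prediction
  if (havePreds) {
    say("[4/6] reusing predictions from %s", predPath)
    records <- read.csv(predPath, stringsAsFactors = FALSE)
  } else {
    say("[4/6] training %d models x %d folds", length(individualModels), config$k)
    inputDim <- dim(volT1[[1]])
    records <- list()
    for (f in seq_len(config$k)) {
      tr <- match(trainIds(plan, f), ids)
      va <- match(valIds(plan, f), ids)
      te <- match(testIds(plan, f), ids)
      addRecords <- function(modelId, split, idx, pred) {
        records[[length(records) + 1]] <<- data.frame(
          subject_id = ids[idx], model = modelId, fold = f, split = split,
          age = age[idx], predicted = pred, stringsAsFactors = FALSE)
      }
      for (m in individualModels) {
        mseed <- stageSeed(seed, "model", f * 100 + match(m, individualModels))
        if (startsWith(m, "mlp")) {
          x <- if (m == "mlp_t1") xT1 else xTof
          hid <- if (m == "mlp_t1") config$mlpT1Hidden else config$mlpTofHidden
          cfg <- config$mlpConfig
          cfg$seed <- mseed
          mod <- trainModel(mlpSpec(colnames(x), hid),
                            x[tr, , drop = FALSE], age[tr],
                            x[va, , drop = FALSE], age[va], cfg)
          valPred <- predictAge(mod, x[va, , drop = FALSE])
          testPred <- predictAge(mod, x[te, , drop = FALSE])
        } else {
          vols <- if (m == "cnn_t1") volT1 else volTof
          cfg <- config$cnnConfig
          cfg$seed <- mseed
          mod <- trainModel(cnnSpec(inputDim), vols[tr], age[tr],
                            vols[va], age[va], cfg)
          valPred <- predictAge(mod, vols[va])
          testPred <- predictAge(mod, vols[te])
        }
        addRecords(m, "val", va, valPred)
        addRecords(m, "test", te, testPred)
        say("  fold %d %-8s test MAE %.2f", f, m, mean(abs(testPred - age[te])))
      }
      addRecords("null", "test", te, rep(mean(age[tr]), length(te)))
    }
    records <- do.call(rbind, records)
    if (!is.null(predPath)) write.csv(records, predPath, row.names = FALSE)
  }

  ## ---- stage 5: fusion, bias correction, BAG
  say("[5/6] stacking, Wilcoxon tests and bias correction")
  getPred <- function(modelId, split, f) {
    r <- records[records$model == modelId & records$split == split &
                   records$fold == f, ]
    r[match(if (split == "val") valIds(plan, f) else testIds(plan, f),
            r$subject_id), ]
  }
  stackWeights <- list()
  for (f in seq_len(config$k)) {
    valAges <- getPred(individualModels[1], "val", f)$age
    valPreds <- lapply(individualModels, function(m) getPred(m, "val", f)$predicted)
    names(valPreds) <- individualModels
    testAges <- getPred(individualModels[1], "test", f)$age
    testSubj <- getPred(individualModels[1], "test", f)$subject_id
    testPreds <- lapply(individualModels, function(m) getPred(m, "test", f)$predicted)
    names(testPreds) <- individualModels
    for (combo in names(modelCombos)) {
      mods <- modelCombos[[combo]]
      w <- fitStack(valPreds[mods], valAges, fold = f)
      stackWeights[[paste(combo, f, sep = ".")]] <- w
      records <- rbind(records, data.frame(
        subject_id = testSubj, model = combo, fold = f, split = "test",
        age = testAges, predicted = applyStack(w, testPreds[mods]),
        stringsAsFactors = FALSE))
    }
  }
  allShares <- do.call(rbind, lapply(seq_len(config$k), function(f) {
    w <- stackWeights[[paste("all_combined", f, sep = ".")]]
    data.frame(fold = f, model = w@models, share = unname(w@shares))
  }))
  stackShares <- vapply(split(allShares$share, allShares$model), mean, 1)
  stackShares <- stackShares[individualModels]

  ## Wilcoxon comparisons on pooled test absolute errors
  pooled <- function(modelId) {
    r <- records[records$model == modelId & records$split == "test", ]
    r <- r[order(r$subject_id), ]
    r$predicted - r$age
  }
  wilcoxPairs <- list(c("cnn_t1", "combined_t1"),
                      c("cnn_tof", "combined_tof"),
                      c("combined_cnn", "all_combined"))
  wilcoxon <- do.call(rbind, lapply(wilcoxPairs, function(pair) {
    cmp <- compareAbsErrors(pooled(pair[1]), pooled(pair[2]))
    data.frame(model_a = pair[1], model_b = pair[2], p = cmp$p.value,
               n = cmp$n, stringsAsFactors = FALSE)
  }))

  ## bias correction for the individual models, per fold
  biasParams <- list()
  records$corrected <- NA_real_
  for (f in seq_len(config$k)) {
    for (m in individualModels) {
      v <- getPred(m, "val", f)
      bp <- fitBias(v$age, v$predicted, model = m, fold = f)
      biasParams[[paste(m, f, sep = ".")]] <- bp
      sel <- records$model == m & records$split == "test" & records$fold == f
      records$corrected[sel] <- correctPredictions(records$predicted[sel],
                                                   records$age[sel], bp)
    }
  }
  test <- records$split == "test" & records$model %in% individualModels
  bagRecords <- data.frame(subject_id = records$subject_id[test],
                           model = records$model[test],
                           bag = computeBAG(records$corrected[test],
                                            records$age[test]),
                           stringsAsFactors = FALSE)

  ## ---- stage 6: metrics and associations
  say("[6/6] metrics and risk-factor associations")
  predSet <- new("PredictionSet", records = records)
  testSet <- new("PredictionSet",
                 records = records[records$split == "test", ])
  metrics <- evaluateByFold(testSet)
  metrics$summary <- metrics$summary[match(modelRowOrder, metrics$summary$model), ]
  rownames(metrics$summary) <- NULL

  corrSet <- new("PredictionSet",
                 records = records[test & !is.na(records$corrected), ])
  corrected <- evaluateByFold(corrSet, useCorrected = TRUE)
  biasComparison <- merge(
    metrics$summary[metrics$summary$model %in% individualModels,
                    c("model", "bias_r")],
    corrected$summary[, c("model", "bias_r")],
    by = "model", suffixes = c("_raw", "_corrected"))

  associations <- associationTable(bagRecords, cohort, factors = config$factors)

  if (!is.null(outDir)) {
    writeCohort(cohort, withFile("cohort.csv"))
    writeFeatureTable(ftT1, withFile("t1_features.csv"))
    if (!is.null(xTof))
      write.csv(data.frame(subject_id = rownames(xTof), xTof, check.names = FALSE),
                withFile("tof_features.csv"), row.names = FALSE)
    writeFoldPlan(plan, withFile("foldplan.csv"))
    write.table(metrics$summary, withFile("metrics_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(associations, withFile("associations.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.csv(bagRecords, withFile("bag.csv"), row.names = FALSE)
    yaml::write_yaml(lapply(stackWeights, function(w)
      list(models = w@models, intercept = w@intercept,
           coefficients = as.list(w@coefficients), fold = w@fold)),
      withFile("stack_weights.yaml"))
  }
  say("done in %.1f s", proc.time()[3] - t0)

  list(cohort = cohort, foldPlan = plan, predictions = predSet,
       metrics = metrics, stackWeights = stackWeights,
       stackShares = stackShares, wilcoxon = wilcoxon,
       biasParams = biasParams, biasComparison = biasComparison,
       bagRecords = bagRecords, associations = associations,
       config = config, seed = seed)
}
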
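## Miniature end-to-end configuration used for structural checks; the
## desk-scale evaluation lives in test-acceptance.R.
tinyConfig <- function() {
  experimentConfig("desk", n = 50, gridSize = 32, cnnDownsample = 2,
                   mlpConfig = trainConfig(lr = 0.02, batchSize = 50, epochs = 25),
                   cnnConfig = cnnTrainConfig(epochs = 1, translationVox = 2))
}

test_that("the experiment bundle has the full evaluation structure", {
  suppressWarnings(res <- runExperiment(tinyConfig(), seed = 5, verbose = FALSE))
  s <- res$metrics$summary
  expect_equal(nrow(s), 10)   # null + 4 individual + 5 combined rows
  expect_equal(s$model,
               c("null", "mlp_t1", "mlp_tof", "cnn_t1", "cnn_tof",
                 "combined_t1", "combined_tof", "combined_mlp",
                 "combined_cnn", "all_combined"))
  expect_true(all(is.finite(s$mae)))
  expect_equal(nrow(res$wilcoxon), 3)
  expect_equal(nrow(res$associations), 20)   # 4 models x 5 factors
  expect_equal(res$associations$q, fdrCorrect(res$associations$p))
  ## normalized stack shares sum to one in every fitted stack
  for (w in res$stackWeights) expect_equal(sum(w@shares), 1, tolerance = 1e-8)
  expect_length(res$stackShares, 4)
  ## every subject appears exactly once in the pooled test BAG per model
  bag <- res$bagRecords
  for (m in c("mlp_t1", "mlp_tof", "cnn_t1", "cnn_tof")) {
    expect_setequal(bag$subject_id[bag$model == m], subjectIds(res$cohort))
    expect_equal(sum(bag$model == m), 50)
  }
  ## bias parameters were fitted per model and fold
  expect_length(res$biasParams, 4 * 5)
})

test_that("identical seeds give bit-identical experiments", {
  suppressWarnings(a <- runExperiment(tinyConfig(), seed = 11, verbose = FALSE))
  suppressWarnings(b <- runExperiment(tinyConfig(), seed = 11, verbose = FALSE))
  expect_identical(a$metrics$summary, b$metrics$summary)
  expect_identical(predictionRecords(a$predictions),
                   predictionRecords(b$predictions))
  expect_identical(a$associations, b$associations)
})

test_that("a run directory supports resuming without retraining", {
  dir <- tempfile("run")
  suppressWarnings(a <- runExperiment(tinyConfig(), seed = 7, outDir = dir,
                                      verbose = FALSE))
  expect_true(file.exists(file.path(dir, "predictions.csv")))
  expect_true(file.exists(file.path(dir, "metrics_summary.tsv")))
  suppressWarnings(b <- runExperiment(tinyConfig(), seed = 7, outDir = dir,
                                      resume = TRUE, verbose = FALSE))
  expect_equal(a$metrics$summary, b$metrics$summary, tolerance = 1e-12)
  expect_equal(a$associations$beta3, b$associations$beta3, tolerance = 1e-12)
})
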
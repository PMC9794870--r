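test_that("the fold plan reproduces the 249-subject validation split", {
  coh <- generateCohort(1658, seed = 21)
  plan <- planFolds(coh, k = 5, valFrac = 0.15, seed = 22)
  expect_equal(vapply(1:5, function(f) length(valIds(plan, f)), 1L),
               rep(249L, 5))
})

test_that("test folds partition the cohort and roles are disjoint", {
  coh <- generateCohort(300, seed = 23)
  plan <- planFolds(coh, seed = 24)
  allTest <- unlist(lapply(1:5, testIds, plan = plan))
  expect_setequal(allTest, subjectIds(coh))
  expect_equal(length(allTest), 300)        # each subject tested exactly once
  for (f in 1:5) {
    expect_length(intersect(valIds(plan, f), testIds(plan, f)), 0)
    expect_length(intersect(trainIds(plan, f), valIds(plan, f)), 0)
    expect_setequal(c(testIds(plan, f), valIds(plan, f), trainIds(plan, f)),
                    subjectIds(coh))
  }
})

test_that("age stratification keeps fold age means within one year", {
  coh <- generateCohort(1658, seed = 25)
  plan <- planFolds(coh, seed = 26)
  mns <- vapply(1:5, function(f)
    mean(ages(coh)[match(testIds(plan, f), subjectIds(coh))]), 1)
  expect_lt(max(mns) - min(mns), 1)
  vmns <- vapply(1:5, function(f)
    mean(ages(coh)[match(valIds(plan, f), subjectIds(coh))]), 1)
  expect_lt(max(abs(vmns - mean(ages(coh)))), 1)
})

test_that("fold planning is deterministic and validates inputs", {
  coh <- generateCohort(120, seed = 27)
  a <- planFolds(coh, seed = 1)
  b <- planFolds(coh, seed = 1)
  expect_identical(a@testFold, b@testFold)
  expect_identical(a@valIds, b@valIds)
  expect_error(planFolds(generateCohort(30, seed = 1)), "at least")
})

test_that("fold plans round-trip through CSV", {
  coh <- generateCohort(100, seed = 28)
  plan <- planFolds(coh, seed = 29)
  path <- tempfile(fileext = ".csv")
  writeFoldPlan(plan, path)
  back <- readFoldPlan(path)
  expect_identical(back@testFold, plan@testFold)
  for (f in 1:5)   # validation membership is a set; file order is canonical
    expect_setequal(back@valIds[[f]], plan@valIds[[f]])
})

test_that("the null model predicts the training mean", {
  ps <- nullModel(c(40, 60), c(30, 50, 70))
  expect_equal(predictionRecords(ps)$predicted, rep(50, 3))
  ps2 <- nullModel(c(40, 60), rep(50, 5))
  expect_equal(suppressWarnings(evaluatePredictions(ps2))$mae, 0)
})

test_that("null-model MAE matches the analytic truncated-normal oracle", {
  coh <- generateCohort(50000, seed = 30)
  a <- ages(coh)
  tr <- a[1:25000]
  te <- a[25001:50000]
  nullMae <- suppressWarnings(evaluatePredictions(te, rep(mean(tr), length(te))))$mae
  ## independent oracle: E|X - c| of the generating truncated normal, by
  ## numerical integration with the recorded parent parameters
  par <- groundTruth(coh)$ageParent
  z <- pnorm(81, par["mean"], par["sd"]) - pnorm(21, par["mean"], par["sd"])
  ctr <- mean(tr)
  oracle <- integrate(function(x)
    abs(x - ctr) * dnorm(x, par["mean"], par["sd"]) / z,
    21, 81, rel.tol = 1e-10)$value
  expect_lt(abs(nullMae / oracle - 1), 0.02)
})

test_that("metrics behave at the degenerate corners", {
  age <- c(30, 45, 60, 75)
  perfect <- evaluatePredictions(age, age)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$bias_r, 0)   # zero-variance gap convention
  expect_warning(nullm <- evaluatePredictions(age, rep(50, 4)), "zero-variance")
  expect_equal(abs(nullm$bias_r), 1)    # gap = const - age
  expect_true(is.nan(nullm$pearson_r))
  expect_error(evaluatePredictions(c(1, 2), c(1, 2)), "at least 3")
})

test_that("bias_r of unbiased noisy predictions vanishes with n", {
  set.seed(31)
  age <- runif(10000, 21, 81)
  m <- evaluatePredictions(age, age + rnorm(10000, 0, 5))
  expect_lt(abs(m$bias_r), 0.05)
})

test_that("metrics are invariant to subject ordering", {
  set.seed(32)
  age <- runif(50, 21, 81)
  pred <- age + rnorm(50, 0, 3)
  perm <- sample(50)
  expect_equal(evaluatePredictions(age, pred),
               evaluatePredictions(age[perm], pred[perm]))
})
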
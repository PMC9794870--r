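test_that("bias parameters recover an exact line", {
  age <- seq(22, 80, length.out = 50)
  bp <- fitBias(age, 0.5 * age + 20)
  expect_equal(bp@alpha, 0.5, tolerance = 1e-10)
  expect_equal(bp@beta, 20, tolerance = 1e-10)
  unb <- fitBias(age, age)
  expect_equal(unb@alpha, 1, tolerance = 1e-10)
  expect_equal(unb@beta, 0, tolerance = 1e-10)
  expect_error(fitBias(rep(50, 10), rnorm(10)), "variance")
  expect_error(fitBias(c(50, 60), c(50, 60)), "at least 3")
})

test_that("bias estimates follow the OLS sampling distribution", {
  set.seed(51)
  age <- runif(10000, 21, 81)
  bp <- fitBias(age, age + rnorm(10000, 0, 3))
  expect_lt(abs(bp@alpha - 1), 0.02)
  expect_lt(abs(bp@beta), 1)
})

test_that("the correction algebra holds exactly", {
  age <- seq(25, 75, length.out = 30)
  ident <- new("BiasParams", alpha = 1, beta = 0, model = "m", fold = 1L)
  pred <- age + rnorm(30)
  expect_equal(correctPredictions(pred, age, ident), pred)
  ## predictions exactly on the bias line correct to the chronological age
  bp <- new("BiasParams", alpha = 0.6, beta = 22, model = "m", fold = 1L)
  online <- 0.6 * age + 22
  expect_equal(correctPredictions(online, age, bp), age, tolerance = 1e-12)
  expect_equal(computeBAG(correctPredictions(online, age, bp), age),
               rep(0, 30), tolerance = 1e-12)
})

test_that("corrected BAG is exactly orthogonal to age on the fitting set", {
  set.seed(52)
  age <- runif(400, 21, 81)
  pred <- 0.55 * age + 21 + rnorm(400, 0, 4)   # biased noisy predictor
  bp <- fitBias(age, pred)
  bag <- computeBAG(correctPredictions(pred, age, bp), age)
  expect_lt(abs(mean(bag)), 1e-10)
  expect_lt(abs(cor(bag, age)), 1e-10)
})

test_that("BAG is a simple difference", {
  age <- c(30, 50, 70)
  expect_equal(computeBAG(age, age), c(0, 0, 0))
  expect_equal(computeBAG(age + 2, age), c(2, 2, 2))
})

test_that("pooled test BAG of a calibrated predictor is centered on zero", {
  set.seed(59)
  n <- 1000
  age <- runif(n, 21, 81)
  pred <- 0.8 * age + 10 + rnorm(n, 0, 4)
  fold <- rep(1:5, length.out = n)
  bag <- numeric(n)
  for (f in 1:5) {
    te <- fold == f
    val <- fold == (f %% 5 + 1)   # disjoint stand-in validation set
    bp <- fitBias(age[val], pred[val])
    bag[te] <- computeBAG(correctPredictions(pred[te], age[te], bp), age[te])
  }
  se <- sd(bag) / sqrt(n)
  expect_lt(abs(mean(bag)), 2 * se)
})

test_that("association regression recovers an injected effect", {
  set.seed(53)
  n <- 5000
  age <- runif(n, 21, 81)
  sex <- rbinom(n, 1, 0.5)
  bmi <- rnorm(n, 27.3, 4.2)
  bag <- 0.8 * scale(bmi)[, 1] + rnorm(n, 0, 1)
  res <- associateBAG(bag, age, sex, bmi, "bmi", "m")
  expect_lt(abs(res$beta3 - 0.8), 0.1)
  expect_lt(abs(res$beta3 - 0.8), 2 * res$se3)
  expect_lt(res$p, 1e-10)
})

test_that("beta3 is invariant to the factor's raw scale", {
  set.seed(54)
  n <- 500
  age <- runif(n, 21, 81)
  sex <- rbinom(n, 1, 0.5)
  f <- rnorm(n, 10, 2)
  bag <- 0.5 * scale(f)[, 1] + rnorm(n)
  r1 <- associateBAG(bag, age, sex, f)
  r2 <- associateBAG(bag, age, sex, 2 * f)
  expect_equal(r1$beta3, r2$beta3, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  expect_error(associateBAG(bag, age, sex, rep(1, n)), "variance")
})

test_that("null effects stay within 3 standard errors", {
  set.seed(55)
  hits <- 0
  for (r in 1:100) {
    n <- 1000
    age <- runif(n, 21, 81)
    sex <- rbinom(n, 1, 0.5)
    f <- rnorm(n)
    bag <- rnorm(n)
    res <- associateBAG(bag, age, sex, f)
    if (abs(res$beta3) < 3 * res$se3) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(fdrCorrect(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrCorrect(0.037), 0.037)
  set.seed(56)
  p <- runif(20)
  q <- fdrCorrect(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in p rank
  expect_error(fdrCorrect(c(0.5, 1.2)), "0, 1")
  expect_error(fdrCorrect(numeric(0)), "empty")
})

test_that("the association table runs one FDR family over models x factors", {
  coh <- generateCohort(200, seed = 57)
  s <- coh@subjects
  set.seed(58)
  bagRecords <- do.call(rbind, lapply(c("m1", "m2"), function(m)
    data.frame(subject_id = s$subject_id, model = m, bag = rnorm(200))))
  res <- associationTable(bagRecords, coh)
  expect_equal(nrow(res), 10)   # 2 models x 5 factors
  expect_equal(res$q, fdrCorrect(res$p))
  ## standardizing before or after subject filtering is equivalent
  sub <- bagRecords[bagRecords$model == "m1", ]
  direct <- associateBAG(sub$bag, s$age, s$sex, s$bmi, "bmi", "m1")
  expect_equal(res$beta3[res$model == "m1" & res$factor == "bmi"],
               direct$beta3, tolerance = 1e-12)
})
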
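test_that("a perfect single model gets coefficient 1 and intercept 0", {
  age <- seq(25, 75, length.out = 40)
  w <- fitStack(list(a = age), age)
  expect_equal(unname(w@coefficients["a"]), 1, tolerance = 1e-8)
  expect_equal(w@intercept, 0, tolerance = 1e-6)
  expect_equal(sum(w@shares), 1)
})

test_that("duplicated models trigger the pseudo-inverse with preserved sum", {
  set.seed(41)
  age <- runif(60, 25, 75)
  pred <- age + rnorm(60, 0, 3)
  single <- fitStack(list(a = pred), age)
  expect_warning(dup <- fitStack(list(a = pred, b = pred), age), "collinear")
  expect_equal(unname(sum(dup@coefficients)),
               unname(single@coefficients["a"]), tolerance = 1e-6)
})

test_that("the stack is optimal on the fitting set and near-optimal on test", {
  set.seed(42)
  sim <- simulateModelPreds(2000, sds = c(3, 6))
  val <- 1:1000
  te <- 1001:2000
  w <- fitStack(lapply(sim$preds, `[`, val), sim$age[val])
  stackVal <- applyStack(w, lapply(sim$preds, `[`, val))
  mseVal <- mean((stackVal - sim$age[val])^2)
  for (m in sim$preds)
    expect_lte(mseVal, mean((m[val] - sim$age[val])^2) + 1e-10)
  stackTest <- applyStack(w, lapply(sim$preds, `[`, te))
  maeTest <- mean(abs(stackTest - sim$age[te]))
  bestIndividual <- min(vapply(sim$preds, function(m)
    mean(abs(m[te] - sim$age[te])), 1))
  expect_lte(maeTest, bestIndividual + 0.1)
})

test_that("applying weights reproduces trivial combinations", {
  w <- new("StackWeights", models = c("a", "b"), intercept = 0,
           coefficients = c(a = 1, b = 0), shares = c(a = 1, b = 0),
           fold = 1L)
  preds <- list(a = c(40, 50), b = c(100, 200))
  expect_equal(applyStack(w, preds), c(40, 50))
  w2 <- new("StackWeights", models = c("a", "b"), intercept = 50,
            coefficients = c(a = 0, b = 0), shares = c(a = 0, b = 0),
            fold = 1L)
  expect_equal(applyStack(w2, preds), c(50, 50))
  expect_error(applyStack(w, list(b = 1:2, a = 3:4)), "mismatch")
})

test_that("identical errors give p = 1 and a uniform shift is detected", {
  e <- rnorm(30)
  expect_warning(res <- compareAbsErrors(e, e), "zero")
  expect_equal(res$p.value, 1)
  set.seed(43)
  a <- rnorm(30, 0, 0.2)
  res2 <- compareAbsErrors(a, a + 1)   # |b| is ~1 larger everywhere
  expect_lt(res2$p.value, 0.001)
})

test_that("the exact branch matches brute-force sign enumeration", {
  set.seed(44)
  for (rep in 1:5) {
    a <- rnorm(20)
    b <- rnorm(20, 0.3)
    res <- compareAbsErrors(a, b)
    expect_equal(res$method, "exact")
    expect_equal(res$p.value, exactSignedRankP(abs(a) - abs(b)),
                 tolerance = 1e-10)
  }
})

test_that("large or tied samples use the tie-corrected normal approximation", {
  set.seed(45)
  a <- rnorm(40)
  b <- rnorm(40, 1.5)
  res <- compareAbsErrors(a, b)
  expect_equal(res$method, "normal approximation")
  expect_lt(res$p.value, 0.05)
})
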
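## hand-built MLP that is linear on its operating range: one hidden layer
## kept strictly in the active ReLU region by a large bias
linearMLP <- function(w) {
  p <- length(w)
  params <- list(
    list(W = diag(p), b = rep(100, p)),       # identity + big offset
    list(W = matrix(w, p, 1), b = -100 * sum(w))
  )
  new("MLPModel",
      spec = list(inputNames = paste0("f", 1:p), hidden = p),
      params = params,
      norm = list(center = rep(0, p), scale = rep(1, p)),
      history = data.frame(), trained = TRUE)
}

test_that("a linear model's SmoothGrad map is |w| for any input and noise", {
  w <- c(2, -3, 0.5, 0)
  mod <- linearMLP(w)
  x <- c(f1 = 1, f2 = -2, f3 = 0.3, f4 = 5)
  expect_equal(unname(predictAge(mod, matrix(x, 1, dimnames = list(NULL, names(x))))),
               sum(w * x), tolerance = 1e-10)
  sm <- smoothGrad(mod, x, nSamples = 10, noiseSd = 0.2, seed = 1)
  expect_equal(unname(sm@values), abs(w), tolerance = 1e-10)
})

test_that("degenerate SmoothGrad equals the plain absolute gradient", {
  set.seed(61)
  x <- matrix(rnorm(200), 40, 5, dimnames = list(paste0("s", 1:40), paste0("f", 1:5)))
  age <- 50 + 6 * x[, 1] - 3 * x[, 2]
  mod <- trainModel(mlpSpec(colnames(x), hidden = 8),
                    x[1:30, ], age[1:30], x[31:40, ], age[31:40],
                    trainConfig(lr = 0.02, batchSize = 30, epochs = 50))
  plain <- smoothGrad(mod, x[1, ], nSamples = 1, noiseSd = 0, seed = 1)
  xs <- (x[1, ] - mod@norm$center) / mod@norm$scale
  grad <- neuroBAG:::mlpInputGradient(mod, matrix(xs, 1))
  expect_equal(unname(plain@values), unname(abs(grad)), tolerance = 1e-10)
  ## sigma -> 0 convergence to the plain gradient
  tiny <- smoothGrad(mod, x[1, ], nSamples = 25, noiseSd = 1e-6, seed = 2)
  expect_lt(max(abs(tiny@values - plain@values)) / max(plain@values), 1e-4)
})

test_that("a single informative input ranks first", {
  w <- c(0, 0, 4, 0, 0)
  mod <- linearMLP(w)
  x <- stats::setNames(rnorm(5), paste0("f", 1:5))
  rk <- mlpImportance(mod, x, nSamples = 5, noiseSd = 0.1, seed = 3)
  expect_equal(rk$feature[1], "f3")
  rk2 <- mlpImportance(mod, x, nSamples = 5, noiseSd = 0.1, seed = 3)
  expect_identical(rk, rk2)   # fixed seed reproduces the ranking
  expect_error(smoothGrad(mod, x, nSamples = 0), ">= 1")
})

test_that("a dominant age slope surfaces in the importance top 3", {
  set.seed(62)
  n <- 300
  p <- 8
  age <- runif(n, 21, 81)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  x[, 4] <- x[, 4] + age / 5        # 10x the slope of the weak features
  for (j in c(1, 2)) x[, j] <- x[, j] + age / 50
  rownames(x) <- paste0("s", 1:n)
  mod <- trainModel(mlpSpec(colnames(x), hidden = 8),
                    x[1:240, ], age[1:240], x[241:300, ], age[241:300],
                    trainConfig(lr = 0.02, batchSize = 80, epochs = 120))
  for (i in 1:5) {
    rk <- mlpImportance(mod, x[i, ], nSamples = 10, noiseSd = 0.1, seed = i)
    expect_true("f4" %in% rk$feature[1:3])
  }
})

test_that("CNN saliency localizes the ventricular age signal", {
  set.seed(63)
  n <- 36
  ages <- runif(n, 21, 81)
  gt <- phantomGroundTruth(ventricleSubjectSd = 0)
  vols <- lapply(seq_len(n), function(i)
    voxels(downsampleVolume(generateBrainVolume(ages[i], 32, gt, seed = i,
                                                noiseSd = 0.02), 2)))
  mod <- trainModel(cnnSpec(c(16, 16, 16)), vols[1:28], ages[1:28],
                    vols[29:36], ages[29:36],
                    cnnTrainConfig(epochs = 6, translationVox = 1,
                                   augmentFraction = 0, seed = 1))
  ## region where the ventricle boundary moves over the age span, at 16^3
  g <- 16
  ctr <- (g + 1) / 2
  co <- expand.grid(x = 1:g, y = 1:g, z = 1:g)
  rad <- function(a) (gt$ventricleBaseFrac + gt$ventricleGrowPerYear * (a - 21)) * g
  ell <- function(r) ((co$x - ctr) / r)^2 + ((co$y - ctr) / (1.3 * r))^2 +
    ((co$z - ctr) / (0.8 * r))^2 <= 1
  region <- array(ell(rad(81)), c(g, g, g))   # ventricle at its largest
  sm <- smoothGrad(mod, vols[[1]], nSamples = 8, noiseSd = 0.05, seed = 2)
  ratio <- mean(sm@values[region]) / mean(sm@values[!region])
  expect_gt(ratio, 1)
})
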
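test_that("MLP layer widths follow the spec", {
  m <- mlpSpec(t1FeatureSchema(), hidden = c(256, 128))
  p <- neuroBAG:::mlpInitParams(223, m@spec$hidden, seed = 1)
  expect_equal(vapply(p, function(l) nrow(l$W), 1L), c(223L, 256L, 128L))
  expect_equal(vapply(p, function(l) ncol(l$W), 1L), c(256L, 128L, 1L))
  expect_length(mlpArchitectureGrid("t1"), 4)
  expect_length(mlpArchitectureGrid("tof"), 4)
})

test_that("CNN halves the grid four times and rejects too-small inputs", {
  m <- cnnSpec(c(48, 48, 48))
  p <- neuroBAG:::cnnInitParams(m@spec, seed = 1)
  r <- neuroBAG:::cnnInitRunning(m@spec)
  x <- array(rnorm(48^3), c(48^3, 1, 1))
  fw <- neuroBAG:::cnnForward(p, r, m@spec, x, training = FALSE, keepCache = TRUE)
  expect_equal(fw$cache$dims[[5]], c(3L, 3L, 3L))   # 48 / 2^4
  expect_length(fw$pred, 1)
  expect_error(cnnSpec(c(8, 8, 8)), "minimum")
})

test_that("augmentation identities hold", {
  v <- array(rnorm(18^3), c(18, 18, 18))
  same <- augmentVolume(v, rotation = c(0, 0, 0), translation = c(0, 0, 0))
  expect_equal(same, v, tolerance = 1e-12, ignore_attr = TRUE)
  shifted <- augmentVolume(v, rotation = c(0, 0, 0), translation = c(5, 0, 0))
  expect_equal(shifted[6:18, , ], v[1:13, , ], tolerance = 1e-12,
               ignore_attr = TRUE)
  a <- augmentVolume(v, seed = 4)
  b <- augmentVolume(v, seed = 4)
  expect_identical(a, b)
})

test_that("an MLP learns a noiseless linear age signal to < 0.5 years", {
  set.seed(1)
  n <- 240
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  age <- 50 + 10 * x[, 1] - 6 * x[, 2] + 4 * x[, 3]
  tr <- 1:180
  va <- 181:240
  rownames(x) <- paste0("s", 1:n)
  mod <- trainModel(mlpSpec(colnames(x), hidden = 16),
                    x[tr, ], age[tr], x[va, ], age[va],
                    trainConfig(lr = 0.02, batchSize = 60, epochs = 200))
  expect_lt(mean(abs(predictAge(mod, x[va, ]) - age[va])), 0.5)
})

test_that("a constant training target is learned as a constant", {
  set.seed(2)
  x <- matrix(rnorm(400), 100, 4, dimnames = list(paste0("s", 1:100), paste0("f", 1:4)))
  age <- rep(50, 100)
  mod <- trainModel(mlpSpec(colnames(x), hidden = 8),
                    x[1:80, ], age[1:80], x[81:100, ], age[81:100],
                    trainConfig(lr = 0.01, batchSize = 40, epochs = 100))
  expect_true(all(abs(predictAge(mod, x) - 50) < 1))
})

test_that("the returned checkpoint has the minimum validation loss", {
  set.seed(3)
  x <- matrix(rnorm(150 * 5), 150, 5, dimnames = list(paste0("s", 1:150), paste0("f", 1:5)))
  age <- 50 + 8 * x[, 1] + rnorm(150, 0, 4)
  mod <- trainModel(mlpSpec(colnames(x), hidden = 8),
                    x[1:100, ], age[1:100], x[101:150, ], age[101:150],
                    trainConfig(lr = 0.05, batchSize = 50, epochs = 60))
  h <- mod@history
  expect_equal(nrow(h), 60)
  ## checkpoint property: recomputed validation loss equals the history minimum
  valLoss <- mean((predictAge(mod, x[101:150, ]) - age[101:150])^2)
  expect_equal(valLoss, min(h$val_loss), tolerance = 1e-8)
  expect_lte(min(h$val_loss), h$val_loss[60])
})

test_that("prediction is deterministic and enforces the feature schema", {
  set.seed(4)
  x <- matrix(rnorm(300), 60, 5, dimnames = list(paste0("s", 1:60), paste0("f", 1:5)))
  age <- 40 + 5 * x[, 1]
  mod <- trainModel(mlpSpec(colnames(x), hidden = 4),
                    x[1:40, ], age[1:40], x[41:60, ], age[41:60],
                    trainConfig(lr = 0.02, batchSize = 40, epochs = 30))
  p1 <- predictAge(mod, x)
  p2 <- predictAge(mod, x)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  expect_error(predictAge(mod, x[, -2]), "missing features: f2")
})

test_that("model checkpoints round-trip through disk", {
  set.seed(7)
  x <- matrix(rnorm(300), 60, 5, dimnames = list(paste0("s", 1:60), paste0("f", 1:5)))
  age <- 40 + 5 * x[, 1]
  mod <- trainModel(mlpSpec(colnames(x), hidden = 4),
                    x[1:40, ], age[1:40], x[41:60, ], age[41:60],
                    trainConfig(lr = 0.02, batchSize = 40, epochs = 20))
  stem <- tempfile("ckpt")
  saveModel(mod, stem)
  expect_true(all(file.exists(paste0(stem, c(".rds", ".yaml", "_log.csv")))))
  back <- loadModel(stem)
  expect_identical(predictAge(back, x), predictAge(mod, x))
})

test_that("training and validation subjects must be disjoint", {
  x <- matrix(rnorm(100), 20, 5, dimnames = list(paste0("s", 1:20), paste0("f", 1:5)))
  expect_error(
    trainModel(mlpSpec(colnames(x), hidden = 4), x[1:15, ], rnorm(15),
               x[14:20, ], rnorm(7), trainConfig(epochs = 2)),
    "disjoint")
})

test_that("non-finite losses abort with a diagnostic", {
  set.seed(5)
  x <- matrix(rnorm(100), 20, 5, dimnames = list(paste0("s", 1:20), paste0("f", 1:5)))
  y <- rnorm(15, 50)
  y[3] <- NaN   # poisons the loss on the first batch
  expect_error(
    trainModel(mlpSpec(colnames(x), hidden = 4), x[1:15, ], y,
               x[16:20, ], rnorm(5, 50), trainConfig(lr = 0.01, epochs = 5)),
    "non-finite")
})

test_that("the CNN trains, checkpoints and predicts deterministically", {
  set.seed(6)
  n <- 40
  ages <- runif(n, 25, 75)
  vols <- lapply(ages, function(a) {
    v <- array(rnorm(16^3, 0, 0.1), c(16, 16, 16))
    v[6:11, 6:11, 6:11] <- v[6:11, 6:11, 6:11] + a / 50
    v
  })
  tr <- 1:30
  va <- 31:40
  mod <- trainModel(cnnSpec(c(16, 16, 16)), vols[tr], ages[tr],
                    vols[va], ages[va],
                    cnnTrainConfig(epochs = 3, translationVox = 2, seed = 1))
  h <- mod@history
  expect_equal(nrow(h), 3)
  valLoss <- mean((predictAge(mod, vols[va]) - ages[va])^2)
  expect_equal(valLoss, min(h$val_loss), tolerance = 1e-8)
  p1 <- predictAge(mod, vols[va])
  expect_identical(p1, predictAge(mod, vols[va]))
  expect_true(all(is.finite(p1)))
  ## same seed reproduces the same trained model
  mod2 <- trainModel(cnnSpec(c(16, 16, 16)), vols[tr], ages[tr],
                     vols[va], ages[va],
                     cnnTrainConfig(epochs = 3, translationVox = 2, seed = 1))
  expect_equal(predictAge(mod2, vols[va]), p1, tolerance = 1e-12)
  ## grid mismatch is rejected
  expect_error(predictAge(mod, array(0, c(18, 18, 18))), "grid")
})
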
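test_that("default cohort reproduces the study demographics", {
  coh <- generateCohort(1658, seed = 11)
  a <- ages(coh)
  expect_true(abs(mean(a) - 49.9) < 1.0)
  expect_true(abs(sd(a) - 13.7) < 1.0)
  expect_true(all(a >= 21 & a <= 81))
  expect_equal(nrow(riskFactors(coh)), 1658)
})

test_that("sample moments converge to configured moments at n = 50,000", {
  coh <- generateCohort(50000, seed = 3)
  rf <- riskFactors(coh)
  s <- coh@subjects
  expect_lt(abs(mean(rf$bp) / 126.0 - 1), 0.02)
  expect_lt(abs(sd(rf$bp) / 16.4 - 1), 0.02)
  expect_lt(abs(mean(rf$bmi) / 27.3 - 1), 0.02)
  expect_lt(abs(sd(rf$bmi) / 4.2 - 1), 0.02)
  expect_lt(abs(mean(rf$whr[s$sex == 0]) / 0.82 - 1), 0.02)
  expect_lt(abs(mean(rf$whr[s$sex == 1]) / 0.94 - 1), 0.02)
  expect_lt(abs(mean(s$sex == 0) / (909 / 1658) - 1), 0.02)
  smk <- tabulate(s$smoking + 1, 5) / 50000
  expect_true(all(abs(smk - c(668, 56, 347, 266, 321) / 1658) < 0.01))
  alc <- tabulate(s$alcohol + 1, 4) / 50000
  expect_true(all(abs(alc - c(112, 458, 963, 125) / 1658) < 0.01))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generateCohort(10, seed = 42)
  b <- generateCohort(10, seed = 42)
  expect_identical(a@subjects, b@subjects)
  c <- generateCohort(10, seed = 43)
  expect_false(identical(a@subjects, c@subjects))
})

test_that("degenerate category distributions collapse to one level", {
  cfg <- cohortConfig(smokingProbs = c(1, 0, 0, 0, 0))
  coh <- generateCohort(50000, seed = 5, config = cfg)
  expect_true(all(coh@subjects$smoking == 0))
})

test_that("non-normalizable probability vectors are rejected", {
  expect_error(cohortConfig(smokingProbs = c(0, 0, 0, 0, 0)), "normalizable")
  expect_error(cohortConfig(alcoholProbs = c(-1, 1, 1, 1)), "normalizable")
  expect_error(cohortConfig(smokingProbs = c(1, 1)), "normalizable")
})

test_that("configured age correlations are injected via the copula", {
  cfg <- cohortConfig(ageCorrelations = c(bp = 0.5, smoking = 0.4))
  coh <- generateCohort(20000, seed = 9, config = cfg)
  s <- coh@subjects
  expect_lt(abs(cor(s$age, s$bp) - 0.5), 0.05)
  expect_gt(cor(s$age, s$smoking), 0.2)  # attenuated by discretization
  ind <- generateCohort(20000, seed = 9)
  expect_lt(abs(cor(ind@subjects$age, ind@subjects$bp)), 0.03)
})

test_that("cohort validity enforces ranges and completeness", {
  coh <- generateCohort(20, seed = 1)
  df <- coh@subjects
  df$age[1] <- 90
  expect_error(new("Cohort", subjects = df), "ages")
  df <- coh@subjects
  df$bmi[2] <- NA
  expect_error(new("Cohort", subjects = df), "missing")
})

test_that("ground truth round-trips through YAML", {
  coh <- generateCohort(15, seed = 2)
  path <- tempfile(fileext = ".yaml")
  writeGroundTruth(groundTruth(coh), path)
  gt <- readGroundTruth(path)
  expect_equal(gt$config$meanAge, 49.9)
  expect_equal(gt$seed, 2)
  expect_equal(unlist(gt$config$smokingProbs),
               unname(groundTruth(coh)$config$smokingProbs), tolerance = 1e-6)
})
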
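#' Demographic configuration for cohort simulation
#'
#' Default marginals reproduce the study population the package emulates:
#' age as a truncated normal with mean 49.9 and sd 13.7 years on \[21, 81\],
#' 909/1658 female, systolic blood pressure N(126.0, 16.4) mmHg, BMI
#' N(27.3, 4.2) kg/m^2, waist-to-hip ratio N(0.82, 0.06) for women and
#' N(0.94, 0.07) for men, smoking category counts (668, 56, 347, 266, 321)
#' and alcohol category counts (112, 458, 963, 125).
#'
#' `ageCorrelations` injects dependence between age and each risk factor
#' through a Gaussian copula on the latent normal scale; the default of zero
#' leaves the factors independent of age.
#'
#' @param meanAge,sdAge,ageRange observed mean and sd (years) of the
#'   truncated age distribution and its range; the matching parent normal
#'   is recovered internally by moment matching
#' @param pFemale probability of sex code 0
#' @param bp,bmi mean and sd of the continuous factors
#' @param whrFemale,whrMale sex-conditional WHR mean and sd
#' @param smokingProbs,alcoholProbs category weights (normalized internally)
#' @param ageCorrelations named latent correlations with age, in \[-1, 1\],
#'   for any of `bp`, `bmi`, `whr`, `smoking`, `alcohol`
#' @param brainAgeSd sd (years) of the hidden per-subject biological
#'   brain-age offset. Synthetic brains look as old as
#'   `age + delta`, where `delta` combines risk-factor effects and this
#'   residual; it is what keeps age decoding imperfect and gives the brain
#'   age gap its real associations
#' @param brainAgeRiskEffects named effects (years per sd of the factor) of
#'   risk factors on the hidden brain-age offset
#' @return a list of class `cohortConfig`
#' @export
#' @examples
#' cfg <- cohortConfig(ageCorrelations = c(bp = 0.4))
#' coh <- generateCohort(200, seed = 1, config = cfg)
#' cor(ages(coh), riskFactors(coh)$bp)
cohortConfig <- function(meanAge = 49.9, sdAge = 13.7, ageRange = c(21, 81),
                         pFemale = 909 / 1658,
                         bp = c(mean = 126.0, sd = 16.4),
                         bmi = c(mean = 27.3, sd = 4.2),
                         whrFemale = c(mean = 0.82, sd = 0.06),
                         whrMale = c(mean = 0.94, sd = 0.07),
                         smokingProbs = c(668, 56, 347, 266, 321),
                         alcoholProbs = c(112, 458, 963, 125),
                         ageCorrelations = c(),
                         brainAgeSd = 5,
                         brainAgeRiskEffects = c(bmi = 0.8, whr = 0.7, bp = 0.6)) {
  checkProbs <- function(p, what, len) {
    if (length(p) != len || any(!is.finite(p)) || any(p < 0) || sum(p) <= 0)
      stop(what, " probabilities are not normalizable", call. = FALSE)
    p / sum(p)
  }
  rho <- c(bp = 0, bmi = 0, whr = 0, smoking = 0, alcohol = 0)
  if (length(ageCorrelations)) {
    bad <- setdiff(names(ageCorrelations), names(rho))
    if (length(bad)) stop("unknown risk factors: ", paste(bad, collapse = ", "))
    if (any(abs(ageCorrelations) > 1)) stop("correlations must lie in [-1, 1]")
    rho[names(ageCorrelations)] <- ageCorrelations
  }
  eff <- c(bp = 0, bmi = 0, whr = 0, smoking = 0, alcohol = 0)
  if (length(brainAgeRiskEffects)) {
    bad <- setdiff(names(brainAgeRiskEffects), names(eff))
    if (length(bad)) stop("unknown risk factors: ", paste(bad, collapse = ", "))
    eff[names(brainAgeRiskEffects)] <- brainAgeRiskEffects
  }
  structure(list(
    meanAge = meanAge, sdAge = sdAge, ageRange = ageRange, pFemale = pFemale,
    bp = bp, bmi = bmi, whrFemale = whrFemale, whrMale = whrMale,
    smokingProbs = checkProbs(smokingProbs, "smoking", 5),
    alcoholProbs = checkProbs(alcoholProbs, "alcohol", 4),
    ageCorrelations = rho, brainAgeSd = brainAgeSd,
    brainAgeRiskEffects = eff
  ), class = "cohortConfig")
}

## latent normal correlated with the age latent, mapped through a marginal
copulaDraw <- function(n, zAge, rho) {
  z <- rho * zAge + sqrt(1 - rho^2) * rnorm(n)
  pnorm(z)
}

ordinalFromU <- function(u, probs) {
  findInterval(u, cumsum(probs), left.open = TRUE)
}

#' Simulate a cohort with known demographic structure
#'
#' Draws ages from a truncated normal, sex from a Bernoulli, continuous risk
#' factors from normals (WHR conditioned on sex) and ordinal factors from
#' categorical distributions, optionally correlated with age via a Gaussian
#' copula. The generating parameters are stored as ground truth on the
#' returned object, so downstream parameter-recovery tests can compare
#' estimates against them.
#'
#' @param n number of subjects (>= 10)
#' @param seed integer seed; identical seeds give identical cohorts
#' @param config a [cohortConfig()]
#' @return a [Cohort-class]
#' @export
#' @examples
#' coh <- generateCohort(100, seed = 7)
#' coh
generateCohort <- function(n, seed = NULL, config = cohortConfig()) {
  stopifnot(is.numeric(n), length(n) == 1)
  if (n < 10) stop("at least 10 subjects are required")
  if (!inherits(config, "cohortConfig")) stop("config must be a cohortConfig()")
  n <- as.integer(n)
  rho <- config$ageCorrelations
  ## meanAge/sdAge are the observed moments of the (truncated) cohort, as
  ## published tables report them; recover the matching parent parameters
  parent <- truncnormParentParams(config$meanAge, config$sdAge,
                                  config$ageRange[1], config$ageRange[2])
  drawn <- withSeed(seed, {
    zAge <- rnorm(n)
    age <- qtruncnorm(pnorm(zAge), parent[["mean"]], parent[["sd"]],
                      config$ageRange[1], config$ageRange[2])
    sex <- as.integer(runif(n) > config$pFemale) # 0 female, 1 male
    uBp <- copulaDraw(n, zAge, rho[["bp"]])
    uBmi <- copulaDraw(n, zAge, rho[["bmi"]])
    uWhr <- copulaDraw(n, zAge, rho[["whr"]])
    uSmk <- copulaDraw(n, zAge, rho[["smoking"]])
    uAlc <- copulaDraw(n, zAge, rho[["alcohol"]])
    whrMean <- ifelse(sex == 0, config$whrFemale[["mean"]], config$whrMale[["mean"]])
    whrSd <- ifelse(sex == 0, config$whrFemale[["sd"]], config$whrMale[["sd"]])
    subjects <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = age,
      sex = sex,
      bp = qnorm(uBp, config$bp[["mean"]], config$bp[["sd"]]),
      bmi = qnorm(uBmi, config$bmi[["mean"]], config$bmi[["sd"]]),
      whr = qnorm(uWhr, whrMean, whrSd),
      smoking = ordinalFromU(uSmk, config$smokingProbs),
      alcohol = ordinalFromU(uAlc, config$alcoholProbs),
      stringsAsFactors = FALSE
    )
    ## hidden biological brain-age offset: risk-factor effects (per sd of
    ## each factor) plus an idiosyncratic residual
    eff <- config$brainAgeRiskEffects
    zOrStop <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
    delta <- rnorm(n, 0, config$brainAgeSd)
    for (f in names(eff))
      if (eff[[f]] != 0) delta <- delta + eff[[f]] * zOrStop(subjects[[f]])
    list(subjects = subjects, delta = delta)
  })
  new("Cohort", subjects = drawn$subjects,
      groundTruth = list(config = unclass(config), seed = seed, n = n,
                         ageParent = parent, deltaBrain = drawn$delta))
}

#' Hidden biological brain ages of a synthetic cohort
#'
#' `age + delta`, where `delta` is the cohort's hidden brain-age offset
#' (see [cohortConfig()]); the synthetic generators make brains look this
#' old. Cohorts without ground truth (e.g. read from CSV) return the
#' chronological ages.
#'
#' @param cohort a [Cohort-class]
#' @return numeric vector of years
#' @export
biologicalAges <- function(cohort) {
  stopifnot(is(cohort, "Cohort"))
  d <- cohort@groundTruth$deltaBrain
  if (is.null(d)) ages(cohort) else ages(cohort) + d
}

#' Read / write cohorts as CSV
#'
#' The CSV holds the subject table only; ground-truth parameters travel
#' separately through [writeGroundTruth()].
#'
#' @param x a [Cohort-class]
#' @param path file path
#' @return `readCohort` returns a [Cohort-class]; `writeCohort` returns
#'   `path` invisibly
#' @export
writeCohort <- function(x, path) {
  stopifnot(is(x, "Cohort"))
  write.csv(x@subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  new("Cohort", subjects = df, groundTruth = list())
}

#' Serialize ground-truth parameters as YAML
#'
#' @param gt a ground-truth list (from [groundTruth()])
#' @param path file path
#' @return `readGroundTruth` returns the parameter list
#' @export
writeGroundTruth <- function(gt, path) {
  yaml::write_yaml(gt, path)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  yaml::read_yaml(path)
}
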
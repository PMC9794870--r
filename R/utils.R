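## Internal helpers.

## Run `expr` under a fixed RNG seed when one is given, restoring the caller's
## RNG state afterwards; with seed = NULL the current RNG stream is used.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

## Truncated normal sampler / quantile via inverse-CDF.
qtruncnorm <- function(p, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + p * (phi - plo), mean, sd)
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  qtruncnorm(runif(n), mean, sd, lower, upper)
}

## analytic mean and sd of a truncated normal with parent (mu, sigma)
truncnormMoments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  lam <- (dnorm(a) - dnorm(b)) / Z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - lam^2)
  c(mean = m, sd = sqrt(v))
}

## parent (mu, sigma) whose truncation to [lower, upper] has the requested
## observed mean and sd (published cohort tables report observed moments)
truncnormParentParams <- function(mean, sd, lower, upper) {
  obj <- function(p) {
    mm <- truncnormMoments(p[1], exp(p[2]), lower, upper)
    (mm["mean"] - mean)^2 + (mm["sd"] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

## Mean absolute deviation of a truncated normal around an arbitrary center,
## by numerical integration (used as an oracle for the null model).
truncnormMeanAbsDev <- function(center, mean, sd, lower, upper) {
  z <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  f <- function(x) abs(x - center) * dnorm(x, mean, sd) / z
  integrate(f, lower, upper, rel.tol = 1e-10)$value
}

## z-score columns; zero-variance columns get scale 1 so they map to 0.
zscoreFit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

zscoreApply <- function(x, norm) {
  sweep(sweep(x, 2, norm$center, "-"), 2, norm$scale, "/")
}

## Deterministic per-stage seed fan-out from one experiment seed.  Offsets are
## spread with a large co-prime multiplier and kept inside the 32-bit range.
stageSeed <- function(seed, stage, index = 0L) {
  if (is.null(seed)) return(NULL)
  offsets <- c(cohort = 1L, morphometry = 2L, atlas = 3L, volumes = 4L,
               folds = 5L, model = 6L, stack = 7L, saliency = 8L,
               association = 9L)
  base <- offsets[[stage]]
  (as.integer(seed) + 97003L * base + 31L * as.integer(index)) %% 2147483647L
}
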
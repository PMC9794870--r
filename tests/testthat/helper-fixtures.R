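## Shared fixtures, all generated in code.

## axis-aligned cylinder mask along z, centered in the x/y plane
cylinderMask <- function(radius, nx = 2 * radius + 9, nz = 24) {
  ctr <- (nx + 1) / 2
  g <- expand.grid(x = seq_len(nx), y = seq_len(nx), z = seq_len(nz))
  array((g$x - ctr)^2 + (g$y - ctr)^2 <= radius^2, dim = c(nx, nx, nz))
}

## odd grid keeps the axis on a voxel center (an even grid straddles it and
## inflates the discrete disc area)
cylinderVolume <- function(radius, intensity = 10, nx = max(2 * radius + 9, 17),
                           nz = 24, noiseSd = 0, seed = 1) {
  m <- cylinderMask(radius, nx, nz)
  v <- array(0, dim(m))
  v[m] <- intensity
  if (noiseSd > 0) {
    set.seed(seed)
    v <- v + array(rnorm(length(v), 0, noiseSd), dim(v))
  }
  new("BrainVolume", voxels = v, spacing = rep(1, 3), modality = "tof")
}

asMask <- function(m, spacing = rep(1, 3)) {
  new("VesselMask", mask = m, spacing = spacing)
}

## Exact two-sided Wilcoxon signed-rank p-value by enumeration over all
## sign assignments, via the generating-polynomial counts of W+.
## Requires distinct nonzero |d|.
exactSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(!anyDuplicated(abs(d)))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  maxW <- n * (n + 1) / 2
  counts <- c(1, rep(0, maxW)) # counts[w+1] = #subsets with rank sum w
  for (rk in r) {
    shifted <- c(rep(0, rk), counts[seq_len(maxW + 1 - rk)])
    counts <- counts + shifted
  }
  total <- 2^n
  pLe <- sum(counts[seq_len(w + 1)]) / total
  pGe <- sum(counts[seq(w + 1, maxW + 1)]) / total
  min(1, 2 * min(pLe, pGe))
}

## simulated stacked-regression setting: true ages plus independent errors
simulateModelPreds <- function(n, sds, ageRange = c(25, 75)) {
  age <- runif(n, ageRange[1], ageRange[2])
  preds <- lapply(sds, function(s) age + rnorm(n, 0, s))
  names(preds) <- paste0("m", seq_along(sds))
  list(age = age, preds = preds)
}
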
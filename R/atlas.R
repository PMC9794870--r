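## Deterministic geometric ROI atlas in phantom space: flow territories
## tile the brain mask, artery-segment regions are tubes around fixed
## piecewise-linear centerline paths.

terrNamesDefault <- c("ACA_L", "ACA_R", "MCA_L", "MCA_R", "PCA_L", "PCA_R")
segNamesDefault <- c("PCA_L", "PCA_R", "MCA_M1_L", "MCA_M1_R",
                     "MCA_M2_L", "MCA_M2_R", "BA", "ICA_L", "ICA_R",
                     "ACA_A1", "ACA_A2")

## Polyline paths in unit coordinates [0,1]^3; x is left-right (L < 0.5),
## y is anterior (low) to posterior (high), z is inferior (low) to
## superior (high).  BA, ACA-A1 and ACA-A2 run along the x midline.
## Coordinates keep each lateralized tube (ROI radius ~0.067 of the grid)
## clear of the x midline and of the anterior/posterior territory
## boundaries (y thirds of the mask, roughly 0.36 and 0.66), so every
## lateralized segment sits inside exactly one territory.
segmentPathsUnit <- function() {
  mir <- function(p) { p[, 1] <- 1 - p[, 1]; p }
  pcaL <- rbind(c(0.41, 0.74, 0.40), c(0.32, 0.82, 0.44))
  m1L <- rbind(c(0.42, 0.50, 0.46), c(0.28, 0.50, 0.46))
  m2L <- rbind(c(0.26, 0.46, 0.50), c(0.20, 0.44, 0.62))
  icaL <- rbind(c(0.40, 0.48, 0.18), c(0.42, 0.50, 0.38))
  list(
    PCA_L = pcaL, PCA_R = mir(pcaL),
    MCA_M1_L = m1L, MCA_M1_R = mir(m1L),
    MCA_M2_L = m2L, MCA_M2_R = mir(m2L),
    BA = rbind(c(0.5, 0.76, 0.16), c(0.5, 0.74, 0.40)),
    ICA_L = icaL, ICA_R = mir(icaL),
    ACA_A1 = rbind(c(0.47, 0.28, 0.42), c(0.47, 0.24, 0.46)),
    ACA_A2 = rbind(c(0.53, 0.26, 0.48), c(0.53, 0.22, 0.62))
  )
}

## prolong a polyline beyond both ends along its terminal directions, so a
## tube drawn around it has no free end inside the ROI that samples it
extendPath <- function(p, ext) {
  d1 <- p[1, ] - p[2, ]
  dn <- p[nrow(p), ] - p[nrow(p) - 1, ]
  unit <- function(v) v / sqrt(sum(v^2))
  rbind(p[1, ] + unit(d1) * ext, p, p[nrow(p), ] + unit(dn) * ext)
}

## Distance (voxels) from every grid voxel to a polyline given in voxel coords.
distanceToPolyline <- function(gridDim, path) {
  g <- expand.grid(x = seq_len(gridDim[1]), y = seq_len(gridDim[2]),
                   z = seq_len(gridDim[3]))
  pts <- as.matrix(g)
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(path) - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a, "-")
    t <- if (len2 > 0) pmin(1, pmax(0, (ap %*% ab) / len2)) else 0
    proj <- sweep(t %*% t(ab), 2, a, "+")
    d2 <- pmin(d2, rowSums((pts - proj)^2))
  }
  array(sqrt(d2), dim = gridDim)
}

#' Build the phantom-space ROI atlas
#'
#' Deterministic partition of an ellipsoidal brain mask into six flow
#' territories (ACA/MCA/PCA x left/right, split at the x midline and by
#' anterior/middle/posterior y-thirds of the mask), with eleven
#' artery-segment regions placed as tubes of radius `roiRadius` around
#' fixed centerline paths. Voxels claimed by several segment tubes go to
#' the nearest path, so segment labels are always disjoint.
#'
#' @param gridSize voxels per axis (>= 32), scalar
#' @param spacing voxel spacing in mm
#' @param roiRadius segment ROI tube radius, in voxels at `gridSize` 48
#'   (scaled proportionally for other grids)
#' @return an [ROIAtlas-class]
#' @export
#' @examples
#' atlas <- makeRoiAtlas(32)
#' atlas
makeRoiAtlas <- function(gridSize = 48, spacing = rep(1, 3), roiRadius = 3.2) {
  stopifnot(length(gridSize) == 1)
  if (gridSize < 32) stop("gridSize must be >= 32")
  g <- as.integer(gridSize)
  dims <- c(g, g, g)
  ctr <- (g + 1) / 2
  ax <- c(0.44, 0.46, 0.40) * g
  coords <- expand.grid(x = seq_len(g), y = seq_len(g), z = seq_len(g))
  inMask <- ((coords$x - ctr) / ax[1])^2 + ((coords$y - ctr) / ax[2])^2 +
    ((coords$z - ctr) / ax[3])^2 <= 1
  brainMask <- array(inMask, dims)

  ## territories: y-thirds of the mask extent, left/right at the x midline
  ys <- range(coords$y[inMask])
  y1 <- ys[1] + (ys[2] - ys[1]) / 3
  y2 <- ys[1] + 2 * (ys[2] - ys[1]) / 3
  band <- ifelse(coords$y <= y1, "ACA", ifelse(coords$y <= y2, "MCA", "PCA"))
  side <- ifelse(coords$x <= ctr, "L", "R")
  terr <- match(paste(band, side, sep = "_"), terrNamesDefault)
  terr[!inMask] <- NA
  territories <- array(ifelse(is.na(terr), 0L, terr), dims)

  ## segment tubes around scaled unit paths, disjoint via nearest path;
  ## synthetic vessels are drawn around paths extended past both ends so the
  ## tube ends (where the distance transform underestimates the radius) fall
  ## outside the ROI that samples them
  paths <- lapply(segmentPathsUnit(), function(p) p * g)
  segDist <- lapply(paths, function(p)
    distanceToPolyline(dims, extendPath(p, 6 * g / 48)))
  roiDist <- lapply(paths, function(p) distanceToPolyline(dims, p))
  distStack <- vapply(roiDist, as.vector, numeric(prod(dims)))
  nearest <- max.col(-distStack, ties.method = "first")
  minDist <- distStack[cbind(seq_len(nrow(distStack)), nearest)]
  rr <- roiRadius * g / 48
  seg <- ifelse(minDist <= rr, nearest, 0L)
  segments <- array(as.integer(seg), dims)

  new("ROIAtlas",
      territories = territories, segments = segments,
      territoryNames = terrNamesDefault, segmentNames = segNamesDefault,
      spacing = spacing, brainMask = brainMask, paths = paths,
      segmentDistance = segDist)
}
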
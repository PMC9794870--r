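## Phantom volume generators with known age effects: a T1-like head with
## age-dependent ventricular enlargement and tissue-shell thinning, and a
## TOF-like angiography volume with age-dependent artery thinning.

#' Ground truth for phantom generation
#'
#' Geometry and age-effect parameters of the phantom generators, in units
#' relative to the grid so the same ground truth scales across resolutions.
#'
#' @param ventricleBaseFrac ventricle semi-axis at age 21, fraction of grid
#' @param ventricleGrowPerYear ventricle semi-axis growth per year (fraction
#'   of grid); the default doubles ventricle volume several times over the
#'   21-81 age span, a deliberately strong atrophy signal
#' @param outerRadiusFrac tissue shell outer semi-axis, fraction of grid
#' @param outerShrinkPerYear outer semi-axis shrinkage per year (fraction of
#'   grid), emulating global atrophy
#' @param tissueIntensity,ventricleIntensity,vesselIntensity raw intensities
#'   before center scaling
#' @param baseRadius named per-segment artery tube radius (voxels at grid 48)
#'   at age 21; `NA` entries are not drawn (useful for single-tube oracles)
#' @param radiusDecayPerYear artery radius loss per year (voxels at grid 48);
#'   radii are clamped at 1 voxel with a warning
#' @param ventricleSubjectSd per-subject anatomical variability of the
#'   ventricle semi-axis (fraction of grid), independent of age
#' @param radiusSubjectSd per-subject, per-segment anatomical variability of
#'   the artery radius (voxels at grid 48), independent of age; real artery
#'   diameters vary substantially between equally old individuals, and this
#'   term is what keeps phantom age decoding imperfect
#' @return a list of class `phantomGroundTruth`
#' @export
phantomGroundTruth <- function(ventricleBaseFrac = 0.07,
                               ventricleGrowPerYear = 0.0022,
                               outerRadiusFrac = 0.42,
                               outerShrinkPerYear = 0.0004,
                               tissueIntensity = 1,
                               ventricleIntensity = 0.05,
                               vesselIntensity = 10,
                               baseRadius = c(PCA_L = 2.6, PCA_R = 2.6,
                                              MCA_M1_L = 3.0, MCA_M1_R = 3.0,
                                              MCA_M2_L = 2.4, MCA_M2_R = 2.4,
                                              BA = 3.2, ICA_L = 3.2, ICA_R = 3.2,
                                              ACA_A1 = 2.4, ACA_A2 = 2.2),
                               radiusDecayPerYear = 0.02,
                               ventricleSubjectSd = 0.008,
                               radiusSubjectSd = 0.25) {
  structure(as.list(environment()), class = "phantomGroundTruth")
}

#' Simulate a T1-like phantom head volume
#'
#' An ellipsoidal bright tissue shell with a central ventricle ellipsoid
#' whose radius grows with age while the shell thins, plus optional
#' Gaussian noise. Intensities are center scaled (zero mean, unit sd over
#' the whole grid, background included), mirroring standard image
#' preprocessing, so the returned volume always has mean 0 and sd 1.
#'
#' @param age chronological age in years
#' @param gridSize voxels per axis (>= 32)
#' @param gt a [phantomGroundTruth()]
#' @param seed integer seed for the noise
#' @param noiseSd Gaussian noise sd on the raw intensity scale
#' @param spacing voxel spacing (mm)
#' @return a [BrainVolume-class] with modality `"t1"`
#' @export
#' @examples
#' vol <- generateBrainVolume(60, gridSize = 32, seed = 1)
#' vol
generateBrainVolume <- function(age, gridSize = 48, gt = phantomGroundTruth(),
                                seed = NULL, noiseSd = 0.05,
                                spacing = rep(1, 3)) {
  if (gridSize < 32) stop("gridSize must be >= 32 per axis")
  g <- as.integer(gridSize)
  ctr <- (g + 1) / 2
  dage <- age - 21
  raw <- withSeed(seed, {
    subjVent <- if (gt$ventricleSubjectSd > 0)
      rnorm(1, 0, gt$ventricleSubjectSd) else 0
    outer <- (gt$outerRadiusFrac - gt$outerShrinkPerYear * dage) * g
    vent <- max(gt$ventricleBaseFrac / 2,
                gt$ventricleBaseFrac + gt$ventricleGrowPerYear * dage + subjVent) * g
    coords <- expand.grid(x = seq_len(g), y = seq_len(g), z = seq_len(g))
    ell <- function(axes) {
      ((coords$x - ctr) / axes[1])^2 + ((coords$y - ctr) / axes[2])^2 +
        ((coords$z - ctr) / axes[3])^2 <= 1
    }
    inTissue <- ell(outer * c(1, 1.05, 0.92))
    inVent <- ell(vent * c(1, 1.3, 0.8))
    r <- ifelse(inVent, gt$ventricleIntensity,
                ifelse(inTissue, gt$tissueIntensity, 0))
    if (noiseSd > 0) r <- r + rnorm(length(r), 0, noiseSd)
    r
  })
  v <- (raw - mean(raw)) / sd(raw)
  new("BrainVolume", voxels = array(v, c(g, g, g)), spacing = spacing,
      modality = "t1")
}

#' Simulate a TOF-like phantom angiography volume
#'
#' Draws bright tubes along the atlas' piecewise-linear artery centerline
#' paths. The tube radius of each segment is
#' `baseRadius - radiusDecayPerYear * (age - 21)`, clamped at 1 voxel (with
#' a warning when the clamp engages), on top of Gaussian background noise.
#' The true per-segment radii are returned alongside the volume so oracle
#' tests can compare estimated diameters against them.
#'
#' @param age chronological age in years
#' @param atlas an [ROIAtlas-class]; the volume is drawn on the atlas grid
#' @param gt a [phantomGroundTruth()]
#' @param seed integer seed for the noise
#' @param noiseSd background noise sd on the raw intensity scale
#' @return a list with elements `volume` (a [BrainVolume-class], modality
#'   `"tof"`) and `radii` (named true tube radii, voxels)
#' @export
#' @examples
#' atlas <- makeRoiAtlas(32)
#' vv <- generateVesselVolume(50, atlas, seed = 1)
#' vv$radii
generateVesselVolume <- function(age, atlas, gt = phantomGroundTruth(),
                                 seed = NULL, noiseSd = 0.5) {
  stopifnot(is(atlas, "ROIAtlas"))
  dims <- dim(atlas@territories)
  gscale <- dims[1] / 48
  out <- withSeed(seed, {
    radii <- gt$baseRadius[atlas@segmentNames] * gscale -
      gt$radiusDecayPerYear * gscale * (age - 21)
    if (gt$radiusSubjectSd > 0)
      radii <- radii + rnorm(length(radii), 0, gt$radiusSubjectSd * gscale)
    clamped <- !is.na(radii) & radii < 1
    if (any(clamped)) {
      warning("tube radius clamped at 1 voxel for: ",
              paste(atlas@segmentNames[clamped], collapse = ", "))
      radii[clamped] <- 1
    }
    names(radii) <- atlas@segmentNames
    raw <- array(0, dims)
    for (s in seq_along(atlas@segmentNames)) {
      if (is.na(radii[s])) next     # segment not drawn
      raw[atlas@segmentDistance[[s]] <= radii[s]] <- gt$vesselIntensity
    }
    if (noiseSd > 0) raw <- raw + array(rnorm(prod(dims), 0, noiseSd), dims)
    list(raw = raw, radii = radii)
  })
  raw <- out$raw
  radii <- out$radii
  vol <- new("BrainVolume", voxels = raw, spacing = atlas@spacing,
             modality = "tof")
  list(volume = vol, radii = radii)
}

#' Down-sample a volume by block averaging
#'
#' Average pooling over `factor`-sized blocks (truncating any remainder),
#' used to derive reduced-resolution network inputs from full phantoms.
#'
#' @param vol a [BrainVolume-class]
#' @param factor integer block size per axis
#' @return a [BrainVolume-class] on the coarser grid
#' @export
downsampleVolume <- function(vol, factor = 2) {
  stopifnot(is(vol, "BrainVolume"), factor >= 1)
  if (factor == 1) return(vol)
  v <- vol@voxels
  d <- dim(v) %/% factor
  v <- v[seq_len(d[1] * factor), seq_len(d[2] * factor), seq_len(d[3] * factor)]
  a <- array(v, c(factor, d[1], factor, d[2], factor, d[3]))
  out <- apply(a, c(2, 4, 6), mean)
  new("BrainVolume", voxels = out, spacing = vol@spacing * factor,
      modality = vol@modality)
}
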
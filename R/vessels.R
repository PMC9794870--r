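## Hand-crafted artery morphometry: threshold segmentation, 3D
## topology-preserving thinning, distance-transform thickness, and
## region-aggregated features.

#' Segment arteries from a TOF-like volume by intensity thresholding
#'
#' Voxels brighter than `mean + k * sd` of the volume are kept; connected
#' components (26-connectivity) smaller than `minVoxels` are removed. The
#' interface accepts any externally produced mask downstream, so a more
#' sophisticated segmenter can be slotted in; thresholding is sufficient
#' for the high-contrast phantoms this package generates.
#'
#' @param tof a [BrainVolume-class] with modality `"tof"`
#' @param k threshold in sd units above the mean
#' @param minVoxels minimum component size in voxels
#' @return a [VesselMask-class]
#' @export
#' @examples
#' atlas <- makeRoiAtlas(32)
#' vv <- generateVesselVolume(40, atlas, seed = 1)
#' mask <- segmentVessels(vv$volume)
segmentVessels <- function(tof, k = 2, minVoxels = 10) {
  stopifnot(is(tof, "BrainVolume"))
  if (tof@modality != "tof") stop("segmentVessels expects a TOF-like volume")
  v <- tof@voxels
  thr <- mean(v) + k * sd(v)
  mask <- v > thr
  if (any(mask) && minVoxels > 1) {
    lab <- cpp_label_components(mask, dim(mask), 26L)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= minVoxels)
    mask <- array(lab %in% keep, dim(mask))
  }
  if (!any(mask))
    stop(sprintf("empty vessel mask after thresholding at %.3f (mean + %g sd)",
                 thr, k))
  new("VesselMask", mask = mask, spacing = tof@spacing)
}

#' Extract a one-voxel-wide vessel centerline
#'
#' Topology-preserving 3D thinning: simple points (whose removal changes
#' neither foreground nor background connectivity) that are not curve
#' endpoints are deleted border-by-border in increasing distance-transform
#' order until the mask is stable. The skeleton preserves the mask's
#' connected-component count and stays within the mask.
#'
#' @param mask a [VesselMask-class]
#' @return a [Centerline-class] (thickness unset; see [computeThickness()])
#' @export
extractCenterline <- function(mask) {
  stopifnot(is(mask, "VesselMask"))
  m <- mask@mask
  if (!any(m)) stop("cannot skeletonize an empty mask")
  edt <- cpp_edt(m, dim(m), mask@spacing)
  sk <- cpp_skeletonize(m, dim(m), edt)
  vox <- which(sk, arr.ind = TRUE)
  colnames(vox) <- c("x", "y", "z")
  new("Centerline", voxels = vox, thickness = rep(NA_real_, nrow(vox)),
      dim = dim(m), spacing = mask@spacing)
}

#' Attach distance-transform thickness to a centerline
#'
#' Computes the exact Euclidean distance transform of the mask (distance in
#' mm from each foreground voxel to the nearest background voxel center,
#' honoring anisotropic spacing; voxels outside the grid count as
#' background) and reads it out at the centerline voxels. At a tube's
#' centerline this distance approximates the local radius; reported
#' diameter features are twice the thickness.
#'
#' @param mask a [VesselMask-class]
#' @param centerline a [Centerline-class] lying inside the mask
#' @return the centerline with `thickness` filled in (mm)
#' @export
computeThickness <- function(mask, centerline) {
  stopifnot(is(mask, "VesselMask"), is(centerline, "Centerline"))
  m <- mask@mask
  inside <- m[centerline@voxels]
  if (!all(inside)) stop("centerline must lie inside the mask")
  edt <- cpp_edt(m, dim(m), mask@spacing)
  centerline@thickness <- edt[centerline@voxels]
  centerline
}

#' Vessel feature schema
#'
#' Ordered names of the 24 artery features: 11 artery-segment mean
#' diameters, 6 territory mean diameters, 6 territory densities, and the
#' whole-head mean diameter.
#'
#' @param atlas an [ROIAtlas-class] providing the region names
#' @return character vector of length 24
#' @export
vesselFeatureSchema <- function(atlas = NULL) {
  sn <- if (is.null(atlas)) segNamesDefault else atlas@segmentNames
  tn <- if (is.null(atlas)) terrNamesDefault else atlas@territoryNames
  c(paste0("diam_seg_", sn), paste0("diam_terr_", tn),
    paste0("density_terr_", tn), "diam_global")
}

#' Aggregate centerline thickness into the 24 artery features
#'
#' Per artery segment: mean diameter (2 x thickness) over centerline voxels
#' inside the segment label. Per territory: mean diameter over centerline
#' voxels in the territory, and density = mask voxels in territory /
#' territory voxels. Plus the whole-head mean diameter. Regions without
#' centerline voxels yield 0 with a warning.
#'
#' @param centerline a [Centerline-class] with thickness computed
#' @param mask the [VesselMask-class] the centerline came from
#' @param atlas an [ROIAtlas-class] on the same grid
#' @return named numeric vector of length 24 (diameters in mm,
#'   densities in \[0, 1\])
#' @export
aggregateVesselFeatures <- function(centerline, mask, atlas) {
  stopifnot(is(centerline, "Centerline"), is(mask, "VesselMask"),
            is(atlas, "ROIAtlas"))
  if (!identical(centerline@dim, dim(atlas@territories)))
    stop("atlas grid does not match the centerline grid")
  if (anyNA(centerline@thickness))
    stop("run computeThickness() before aggregating")
  diam <- 2 * centerline@thickness
  segLab <- atlas@segments[centerline@voxels]
  terrLab <- atlas@territories[centerline@voxels]
  nSeg <- length(atlas@segmentNames)
  nTerr <- length(atlas@territoryNames)
  meanOr0 <- function(x, what) {
    if (length(x) == 0) {
      warning("no centerline voxels in ", what, "; reporting 0")
      0
    } else mean(x)
  }
  segDiam <- vapply(seq_len(nSeg), function(s)
    meanOr0(diam[segLab == s], paste("segment", atlas@segmentNames[s])), 1)
  terrDiam <- vapply(seq_len(nTerr), function(t)
    meanOr0(diam[terrLab == t], paste("territory", atlas@territoryNames[t])), 1)
  terrDens <- vapply(seq_len(nTerr), function(t) {
    vox <- atlas@territories == t
    sum(mask@mask & vox) / sum(vox)
  }, 1)
  out <- c(segDiam, terrDiam, terrDens, mean(diam))
  names(out) <- vesselFeatureSchema(atlas)
  out
}

#' Full vessel morphometry pipeline for one volume
#'
#' Segmentation, centerline extraction, thickness computation and feature
#' aggregation in one deterministic call.
#'
#' @param tof a TOF-like [BrainVolume-class]
#' @param atlas an [ROIAtlas-class] on the same grid
#' @param k,minVoxels segmentation parameters, see [segmentVessels()]
#' @return named numeric vector of 24 features
#' @export
extractVesselFeatures <- function(tof, atlas, k = 2, minVoxels = 10) {
  mask <- segmentVessels(tof, k = k, minVoxels = minVoxels)
  ## one distance transform serves both the thinning order and the thickness
  m <- mask@mask
  edt <- cpp_edt(m, dim(m), mask@spacing)
  sk <- cpp_skeletonize(m, dim(m), edt)
  vox <- which(sk, arr.ind = TRUE)
  colnames(vox) <- c("x", "y", "z")
  cl <- new("Centerline", voxels = vox, thickness = edt[vox],
            dim = dim(m), spacing = mask@spacing)
  aggregateVesselFeatures(cl, mask, atlas)
}
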
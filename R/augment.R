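## Random rigid augmentation for volumetric training.

eulerRotation <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

## deterministic core: rotate about the volume center, then translate;
## trilinear interpolation, out-of-field voxels filled with the volume
## median (the background intensity in these phantoms)
applyAugmentation <- function(vol, rotation = c(0, 0, 0),
                              translation = c(0, 0, 0), fill = NULL) {
  stopifnot(length(dim(vol)) == 3)
  if (is.null(fill)) fill <- median(vol)
  R <- eulerRotation(rotation)
  cpp_affine_resample(vol, dim(vol), t(R), as.numeric(translation), fill)
}

#' Randomly rotate and translate a volume
#'
#' Training-time augmentation: rotation angles drawn uniformly in
#' `[-rotationDeg, +rotationDeg]` per axis and integer translations in
#' `[-translationVox, +translationVox]` voxels per axis, applied with
#' trilinear interpolation about the volume center. Out-of-field voxels are
#' filled with the volume median (the phantom background). Passing explicit
#' `rotation` / `translation` values bypasses the random draw.
#'
#' @param x a [BrainVolume-class] or 3D array
#' @param rotationDeg,translationVox random draw ranges
#' @param rotation,translation explicit parameters (degrees / voxels),
#'   overriding the random draw
#' @param seed integer seed for the random draw
#' @return augmented object of the same type
#' @export
#' @examples
#' v <- array(rnorm(20^3), c(20, 20, 20))
#' shifted <- augmentVolume(v, rotation = c(0, 0, 0), translation = c(3, 0, 0))
#' all.equal(shifted[4:20, , ], v[1:17, , ])
augmentVolume <- function(x, rotationDeg = 5, translationVox = 10,
                          rotation = NULL, translation = NULL, seed = NULL) {
  vol <- if (is(x, "BrainVolume")) x@voxels else x
  if (is.null(rotation) || is.null(translation)) {
    drawn <- withSeed(seed, list(
      rot = runif(3, -rotationDeg, rotationDeg),
      tr = sample(-translationVox:translationVox, 3, replace = TRUE)))
    if (is.null(rotation)) rotation <- drawn$rot
    if (is.null(translation)) translation <- drawn$tr
  }
  out <- applyAugmentation(vol, rotation, translation)
  if (is(x, "BrainVolume"))
    new("BrainVolume", voxels = out, spacing = x@spacing, modality = x@modality)
  else out
}
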
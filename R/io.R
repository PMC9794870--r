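## NIfTI I/O for volumes and atlases.

#' Write / read volumes as NIfTI
#'
#' @param x a [BrainVolume-class] or [ROIAtlas-class]
#' @param path output path (`.nii` or `.nii.gz`)
#' @param modality modality tag to attach on read
#' @return `readVolume` returns a [BrainVolume-class]
#' @export
writeVolume <- function(x, path) {
  stopifnot(is(x, "BrainVolume"))
  img <- RNifti::asNifti(x@voxels, pixdim = x@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, modality = c("t1", "tof")) {
  img <- RNifti::readNifti(path)
  new("BrainVolume", voxels = array(as.numeric(img), dim(img)),
      spacing = RNifti::pixdim(img)[1:3], modality = match.arg(modality))
}

#' Save / load a trained model checkpoint
#'
#' Writes `<stem>.rds` (parameters), `<stem>.yaml` (architecture spec, for
#' inspection without loading) and `<stem>_log.csv` (per-epoch training and
#' validation losses).
#'
#' @param model a trained [MLPModel-class] or [CNNModel-class]
#' @param stem output path stem
#' @return `loadModel` returns the model
#' @export
saveModel <- function(model, stem) {
  stopifnot(is(model, "MLPModel") || is(model, "CNNModel"))
  saveRDS(model, paste0(stem, ".rds"))
  yaml::write_yaml(c(list(class = class(model)[1]), model@spec),
                   paste0(stem, ".yaml"))
  if (nrow(model@history))
    write.csv(model@history, paste0(stem, "_log.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname saveModel
#' @export
loadModel <- function(stem) {
  readRDS(paste0(stem, ".rds"))
}

#' Write a CNN saliency map as NIfTI
#'
#' @param map a [SaliencyMap-class] with voxel-shaped values
#' @param path output path
#' @param spacing voxel spacing of the map grid (mm)
#' @return `path`, invisibly
#' @export
writeSaliency <- function(map, path, spacing = rep(1, 3)) {
  stopifnot(is(map, "SaliencyMap"), is.array(map@values))
  RNifti::writeNifti(RNifti::asNifti(map@values, pixdim = spacing), path)
  invisible(path)
}

#' Write an atlas as a pair of NIfTI label volumes
#'
#' Writes `<stem>_territories.nii.gz` and `<stem>_segments.nii.gz`.
#'
#' @param atlas an [ROIAtlas-class]
#' @param stem output path stem
#' @return the two paths, invisibly
#' @export
writeAtlas <- function(atlas, stem) {
  stopifnot(is(atlas, "ROIAtlas"))
  p1 <- paste0(stem, "_territories.nii.gz")
  p2 <- paste0(stem, "_segments.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(atlas@territories, pixdim = atlas@spacing), p1)
  RNifti::writeNifti(RNifti::asNifti(atlas@segments, pixdim = atlas@spacing), p2)
  invisible(c(p1, p2))
}
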
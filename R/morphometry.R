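## T1 morphometry simulation: a 223-column feature table shaped like the
## output of a cortical/subcortical segmentation pipeline (surface area,
## gray matter volume and average thickness for 64 cortical structures,
## plus 31 subcortical/global volumes including the total brain volume).

cortexRegions <- c(
  "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus", "entorhinal",
  "fusiform", "inferiorparietal", "inferiortemporal", "isthmuscingulate",
  "lateraloccipital", "lateralorbitofrontal", "lingual", "medialorbitofrontal",
  "middletemporal", "parahippocampal", "paracentral", "parsopercularis",
  "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
  "posteriorcingulate", "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "transversetemporal", "insula",
  "frontalpole"
)

subcorticalStructures <- c(
  "Left-Lateral-Ventricle", "Right-Lateral-Ventricle",
  "Left-Inf-Lat-Vent", "Right-Inf-Lat-Vent", "3rd-Ventricle", "4th-Ventricle",
  "Left-Cerebellum-White-Matter", "Right-Cerebellum-White-Matter",
  "Left-Cerebellum-Cortex", "Right-Cerebellum-Cortex",
  "Left-Thalamus", "Right-Thalamus", "Left-Caudate", "Right-Caudate",
  "Left-Putamen", "Right-Putamen", "Left-Pallidum", "Right-Pallidum",
  "Left-Hippocampus", "Right-Hippocampus", "Left-Amygdala", "Right-Amygdala",
  "Left-Accumbens-area", "Right-Accumbens-area",
  "Left-VentralDC", "Right-VentralDC",
  "Brain-Stem", "CSF", "WM-hypointensities", "CC-Mid-Anterior"
)

#' T1 morphometry feature schema
#'
#' Ordered names of the 223 simulated T1 features: 64 cortical structures
#' (32 regions x 2 hemispheres) with three measures each (surface area, gray
#' matter volume, average thickness), 30 subcortical volumes, and the total
#' brain volume. Only the total of 223 is treated as fixed; the name list is
#' a plausible segmentation-pipeline naming and is also shipped as
#' `inst/extdata/t1_feature_schema.txt`.
#'
#' @return character vector of length 223
#' @export
#' @examples
#' length(t1FeatureSchema())
t1FeatureSchema <- function() {
  cortical <- as.vector(t(outer(
    paste0(rep(c("lh", "rh"), each = length(cortexRegions)), "_",
           rep(cortexRegions, 2)),
    c("area", "grayvol", "thickness"), paste, sep = "_"
  )))
  c(cortical, paste0("vol_", subcorticalStructures), "TotalBrainVol")
}

featureKind <- function(names) {
  kind <- rep("volume", length(names))
  kind[grepl("_area$", names)] <- "area"
  kind[grepl("_thickness$", names)] <- "thickness"
  kind
}

#' Ground truth for morphometry simulation
#'
#' Defines, for each of the 223 features, an intercept, an age slope, a sex
#' offset, risk-factor slopes (on standardized factors) and a noise sd, plus
#' a shared per-subject "head size" factor loading on area/volume features.
#' Feature values follow
#' `intercept + ageSlope * (age - 50) + sexOffset * sex +
#'  sum(riskSlope * z(factor)) + loading * headSize + N(0, sd)`.
#'
#' Defaults emulate aging morphometry: volumes and thicknesses shrink with
#' age (about 0.5-1.5% of scale per decade), ventricular and CSF volumes
#' grow, male brains are slightly larger, and higher BMI is associated with
#' slightly lower gray-matter volumes. `noiseScale = 0` and
#' `headSizeSd = 0` give exactly linear, noiseless features.
#'
#' @param seed integer seed used to draw the per-feature coefficients
#' @param noiseScale independent noise sd, as a fraction of feature scale
#' @param headSizeSd sd of the shared per-subject size factor
#' @param riskSlopes named list mapping risk factors to slope scale
#'   (fraction of feature scale per 1 sd of the factor) applied to
#'   volume/area features
#' @return a list of class `morphometryGroundTruth` with per-feature vectors
#' @export
morphometryGroundTruth <- function(seed = 1, noiseScale = 0.08,
                                   headSizeSd = 1,
                                   riskSlopes = list(bmi = -0.01, bp = -0.004)) {
  nm <- t1FeatureSchema()
  kind <- featureKind(nm)
  scale <- ifelse(kind == "thickness", 2.5,
                  ifelse(kind == "area", 2000, 4000))
  ventricular <- grepl("Ventricle|Inf-Lat-Vent|CSF|hypointensities", nm)
  withSeed(seed, {
    p <- length(nm)
    slopeFrac <- -runif(p, 0.004, 0.012)          # shrinkage per year
    slopeFrac[ventricular] <- runif(sum(ventricular), 0.01, 0.02)
    ageSlope <- slopeFrac * scale
    sexOffset <- ifelse(kind == "thickness", 0, 0.06 * scale * runif(p, 0.5, 1.5))
    loading <- ifelse(kind == "thickness", 0, 0.06 * scale)
    noiseSd <- noiseScale * scale
    rs <- matrix(0, p, 5, dimnames = list(nm, c("bp", "bmi", "whr", "smoking", "alcohol")))
    for (f in names(riskSlopes)) {
      rs[kind != "thickness", f] <- riskSlopes[[f]] * scale[kind != "thickness"]
    }
    structure(list(
      featureNames = nm, intercept = 10 * scale, ageSlope = ageSlope,
      sexOffset = sexOffset, riskSlopes = rs, noiseSd = noiseSd,
      headSizeLoading = loading, headSizeSd = headSizeSd, seed = seed
    ), class = "morphometryGroundTruth")
  })
}

#' Simulate a T1 morphometry feature table
#'
#' Each feature is an affine function of age, sex and standardized risk
#' factors plus a shared head-size factor and independent Gaussian noise,
#' per the coefficients in `gt`. The result always has exactly 223 columns.
#'
#' @param cohort a [Cohort-class]
#' @param gt a [morphometryGroundTruth()]
#' @param seed integer seed for the noise draws
#' @return a [FeatureTable-class] with 223 features and the cohort's
#'   covariates in `colData`
#' @export
#' @examples
#' coh <- generateCohort(50, seed = 1)
#' ft <- generateMorphometry(coh, seed = 2)
#' dim(featureMatrix(ft))
generateMorphometry <- function(cohort, gt = morphometryGroundTruth(), seed = NULL) {
  stopifnot(is(cohort, "Cohort"))
  if (!inherits(gt, "morphometryGroundTruth"))
    stop("gt must be a morphometryGroundTruth()")
  df <- cohort@subjects
  need <- c("age", "sex", "bp", "bmi", "whr", "smoking", "alcohol")
  if (!all(need %in% names(df)) || anyNA(df[need]))
    stop("cohort has missing risk factors")
  n <- nrow(df)
  p <- length(gt$featureNames)
  zrisk <- scale(as.matrix(df[, colnames(gt$riskSlopes)]))
  zrisk[is.nan(zrisk)] <- 0 # zero-variance factor in tiny cohorts
  ## features respond to the hidden biological brain age, not the
  ## chronological age, so a brain age gap exists to be found
  effAge <- biologicalAges(cohort)
  mu <- matrix(gt$intercept, n, p, byrow = TRUE) +
    outer(effAge - 50, gt$ageSlope) +
    outer(df$sex, gt$sexOffset) +
    zrisk %*% t(gt$riskSlopes)
  m <- withSeed(seed, {
    head <- rnorm(n, 0, gt$headSizeSd)
    mu + outer(head, gt$headSizeLoading) +
      matrix(rnorm(n * p, 0, 1), n, p) * matrix(gt$noiseSd, n, p, byrow = TRUE)
  })
  dimnames(m) <- list(df$subject_id, gt$featureNames)
  FeatureTable(m, cohort = cohort, groundTruth = gt)
}

#' Construct a FeatureTable
#'
#' @param features numeric matrix, subjects in rows, named features in
#'   columns
#' @param cohort optional [Cohort-class] supplying per-subject covariates
#' @param groundTruth optional generating parameters to store in metadata
#' @return a [FeatureTable-class]
#' @export
FeatureTable <- function(features, cohort = NULL, groundTruth = NULL) {
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  cd <- if (!is.null(cohort)) {
    stopifnot(identical(rownames(features), subjectIds(cohort)))
    DataFrame(cohort@subjects[, -1, drop = FALSE], row.names = rownames(features))
  } else {
    DataFrame(row.names = rownames(features))
  }
  se <- SummarizedExperiment(assays = list(features = t(features)), colData = cd)
  out <- new("FeatureTable", se)
  metadata(out)$groundTruth <- groundTruth
  out
}

#' Read / write feature tables as CSV
#'
#' Subjects in rows (first column `subject_id`), features in named columns.
#'
#' @param x a [FeatureTable-class]
#' @param path file path
#' @return `readFeatureTable` returns a [FeatureTable-class]
#' @export
writeFeatureTable <- function(x, path) {
  m <- featureMatrix(x)
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject_id
  FeatureTable(m)
}
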
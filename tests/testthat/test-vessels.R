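test_that("thresholding recovers a noiseless tube exactly", {
  vol <- cylinderVolume(3, intensity = 10, noiseSd = 0)
  mask <- segmentVessels(vol, k = 2)
  expect_identical(voxels(mask), voxels(vol) > 0)
})

test_that("an all-background volume raises an error naming the threshold", {
  vol <- new("BrainVolume", voxels = array(0, c(16, 16, 16)),
             spacing = rep(1, 3), modality = "tof")
  expect_error(segmentVessels(vol), "threshold")
})

test_that("small components are removed and modality is checked", {
  v <- array(0, c(20, 20, 20))
  v[3:15, 10, 10] <- 10       # a 13-voxel line
  v[18, 18, 18] <- 10         # isolated speck
  vol <- new("BrainVolume", voxels = v, spacing = rep(1, 3), modality = "tof")
  mask <- segmentVessels(vol, k = 2, minVoxels = 5)
  expect_equal(sum(voxels(mask)), 13)
  t1 <- new("BrainVolume", voxels = v, spacing = rep(1, 3), modality = "t1")
  expect_error(segmentVessels(t1), "TOF")
})

test_that("segmented tube voxel count matches the analytic cylinder volume", {
  vol <- cylinderVolume(3, nz = 40, noiseSd = 0.3, seed = 2)
  mask <- segmentVessels(vol, k = 2)
  analytic <- pi * 3^2 * 40
  expect_lt(abs(sum(voxels(mask)) / analytic - 1), 0.1)
})

test_that("a straight cylinder thins to a single centered path", {
  mask <- asMask(cylinderMask(3, nx = 15, nz = 24))
  cl <- extractCenterline(mask)
  ## one 26-connected component
  sk <- array(FALSE, cl@dim)
  sk[cl@voxels] <- TRUE
  lab <- neuroBAG:::cpp_label_components(sk, dim(sk), 26L)
  expect_equal(max(lab), 1)
  ## all skeleton voxels within 1 voxel of the true axis (x = y = 8)
  expect_true(all(abs(cl@voxels[, "x"] - 8) <= 1))
  expect_true(all(abs(cl@voxels[, "y"] - 8) <= 1))
  ## 1-voxel wide: no voxel has its full 3x3x3 neighborhood inside the skeleton
  pad <- array(FALSE, cl@dim + 2)
  pad[2:(cl@dim[1] + 1), 2:(cl@dim[2] + 1), 2:(cl@dim[3] + 1)] <- sk
  full <- vapply(seq_len(nrow(cl@voxels)), function(i) {
    v <- cl@voxels[i, ] + 1
    all(pad[(v[1] - 1):(v[1] + 1), (v[2] - 1):(v[2] + 1), (v[3] - 1):(v[3] + 1)])
  }, TRUE)
  expect_false(any(full))
  ## skeleton voxels all lie inside the mask
  expect_true(all(voxels(mask)[cl@voxels]))
})

test_that("a single isolated voxel is its own skeleton", {
  m <- array(FALSE, c(16, 16, 16))
  m[8, 8, 8] <- TRUE
  cl <- extractCenterline(asMask(m))
  expect_equal(unname(cl@voxels), matrix(c(8L, 8L, 8L), 1))
})

test_that("thinning preserves the component count of disjoint tubes", {
  m <- cylinderMask(2, nx = 24, nz = 20)
  m2 <- m
  m2[, , ] <- FALSE
  m2[18:22, 18:22, ] <- m[8:12, 8:12, ]   # copy tube to a far corner
  both <- m | m2
  cl <- extractCenterline(asMask(both))
  sk <- array(FALSE, cl@dim)
  sk[cl@voxels] <- TRUE
  expect_equal(max(neuroBAG:::cpp_label_components(sk, dim(sk), 26L)), 2)
})

test_that("centerline thickness matches the analytic cylinder radius", {
  for (r in c(2, 4)) {
    mask <- asMask(cylinderMask(r, nz = 30))
    cl <- computeThickness(mask, extractCenterline(mask))
    expect_lte(max(abs(cl@thickness - r)), 1)   # skeleton ends sit 1 voxel in
    expect_lte(abs(mean(2 * cl@thickness) - 2 * r), 1)
  }
})

test_that("anisotropic spacing is honored by the distance transform", {
  ## tube along z with radius 3 voxels in-plane, spacing (1, 1, 2) mm
  mask <- asMask(cylinderMask(3, nz = 20), spacing = c(1, 1, 2))
  cl <- computeThickness(mask, extractCenterline(mask))
  expect_lt(abs(mean(cl@thickness) - 3), 1)
})

test_that("a single-voxel mask has thickness one voxel spacing", {
  m <- array(FALSE, c(16, 16, 16))
  m[8, 8, 8] <- TRUE
  mask <- asMask(m)
  cl <- computeThickness(mask, extractCenterline(mask))
  expect_equal(unname(cl@thickness), 1)   # distance to adjacent background center
})

test_that("aggregation yields exactly 24 features with correct regions", {
  atlas <- makeRoiAtlas(48)
  vv <- generateVesselVolume(45, atlas, seed = 3)
  f <- extractVesselFeatures(vv$volume, atlas)
  expect_length(f, 24)
  expect_identical(names(f), vesselFeatureSchema(atlas))
  expect_true(all(f[grepl("^density", names(f))] >= 0 &
                  f[grepl("^density", names(f))] <= 1))
})

test_that("estimated segment diameters track the known phantom radii", {
  atlas <- makeRoiAtlas(48)
  gt <- phantomGroundTruth(radiusSubjectSd = 0)
  vv <- generateVesselVolume(40, atlas, gt, noiseSd = 0)
  f <- extractVesselFeatures(vv$volume, atlas)
  est <- f[paste0("diam_seg_", names(vv$radii))]
  expect_true(all(abs(est - 2 * vv$radii) <= 1))
})

test_that("empty regions aggregate to 0 with a warning", {
  atlas <- makeRoiAtlas(32)
  m <- array(FALSE, dim(atlas@territories))
  m[atlas@segments == which(atlas@segmentNames == "MCA_M1_L")] <- TRUE
  mask <- asMask(m)
  cl <- computeThickness(mask, extractCenterline(mask))
  w <- capture_warnings(f <- aggregateVesselFeatures(cl, mask, atlas))
  expect_true(any(grepl("no centerline", w)))   # every empty region warns
  expect_equal(unname(f["diam_terr_PCA_R"]), 0)
  expect_equal(unname(f["density_terr_PCA_R"]), 0)
})

test_that("grid mismatches are rejected", {
  atlas <- makeRoiAtlas(32)
  mask <- asMask(cylinderMask(2, nx = 20, nz = 20))
  cl <- computeThickness(mask, extractCenterline(mask))
  expect_error(aggregateVesselFeatures(cl, mask, atlas), "grid")
})

test_that("diameter estimates are monotone in the true radius", {
  est <- vapply(2:6, function(r) {
    mask <- asMask(cylinderMask(r, nz = 24))
    cl <- computeThickness(mask, extractCenterline(mask))
    mean(2 * cl@thickness)
  }, 1)
  expect_equal(cor(est, 2:6, method = "spearman"), 1)
})

test_that("density increases when a second tube enters a territory", {
  atlas <- makeRoiAtlas(32)
  one <- array(FALSE, dim(atlas@territories))
  one[atlas@segments == which(atlas@segmentNames == "MCA_M1_L")] <- TRUE
  two <- one
  two[atlas@segments == which(atlas@segmentNames == "MCA_M2_L")] <- TRUE
  terr <- which(atlas@territoryNames == "MCA_L")
  dens <- function(m) sum(m & atlas@territories == terr) /
    sum(atlas@territories == terr)
  expect_gt(dens(two), dens(one))
})

test_that("the full vessel pipeline is deterministic", {
  atlas <- makeRoiAtlas(32)
  vv <- suppressWarnings(generateVesselVolume(58, atlas, seed = 13))  # clamp at 32^3 is expected
  f1 <- extractVesselFeatures(vv$volume, atlas)
  f2 <- extractVesselFeatures(vv$volume, atlas)
  expect_identical(f1, f2)
})
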
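makeCapsuleVolume <- function(centerlines, r = 0.15, h = 0.02,
                              shape = c(50L, 80L, 40L), fuse = FALSE,
                              vs = NULL) {
  if (is.null(vs)) vs <- rep(h, 3)
  specs <- lapply(centerlines, function(cl) mitoSpec(cl, r))
  generateVolume3D(specs, voxelSizeUm = vs, volumeShape = shape, fuse = fuse)
}

test_that("component labeling follows 26-connectivity", {
  v <- array(0L, dim = c(10, 10, 10))
  v[2:4, 2:4, 2:4] <- 1L
  v[6:8, 6:8, 6:8] <- 1L
  lv <- labelComponents(labelVolume(v, rep(0.01, 3)))
  expect_equal(max(voxels(lv)), 2L)
  # touching at a single voxel corner: one 26-connected component
  v2 <- array(0L, dim = c(10, 10, 10))
  v2[2:4, 2:4, 2:4] <- 1L
  v2[5:7, 5:7, 5:7] <- 1L
  lv2 <- labelComponents(labelVolume(v2, rep(0.01, 3)))
  expect_equal(max(voxels(lv2)), 1L)
  # empty volume: zero labels
  lv0 <- labelComponents(labelVolume(array(0L, dim = c(4, 4, 4)), rep(0.01, 3)))
  expect_equal(max(voxels(lv0)), 0L)
})

test_that("watershed splits fused objects and conserves every voxel", {
  r <- 0.2
  c1 <- c(0.5, 0.5, 0.5)
  sphere <- function(c0) rbind(c0, c0 + c(1e-6, 0, 0))
  # two spheres fused by a neck
  gv <- makeCapsuleVolume(list(sphere(c1), sphere(c1 + c(1.8 * r, 0, 0))),
                          r = r, shape = c(50L, 70L, 50L), fuse = TRUE)
  mask <- voxels(gv$volume) == 1L
  split <- watershedSplit(mask, voxelSize(gv$volume))
  expect_equal(max(split), 2L)
  expect_equal(sum(split > 0), sum(mask)) # conservation
  sph <- 4 / 3 * pi * r^3
  for (i in 1:2)
    expect_lt(abs(objectVolume(split == i, voxelSize(gv$volume)) - sph) / sph,
              0.1)
  # a single capsule stays unsplit
  gv1 <- makeCapsuleVolume(list(rbind(c(0.3, 0.4, 0.4), c(1.2, 0.4, 0.4))))
  m1 <- voxels(gv1$volume) == 1L
  s1 <- watershedSplit(m1, voxelSize(gv1$volume))
  expect_equal(max(s1), 1L)
  expect_identical(s1 > 0, m1)
  # three-bead chain
  gv3 <- makeCapsuleVolume(list(sphere(c1), sphere(c1 + c(1.8 * r, 0, 0)),
                                sphere(c1 + c(3.6 * r, 0, 0))),
                           r = r, shape = c(50L, 90L, 50L), fuse = TRUE)
  s3 <- watershedSplit(voxels(gv3$volume) == 1L, voxelSize(gv3$volume))
  expect_equal(max(s3), 3L)
})

test_that("object volume is exact voxel arithmetic", {
  m <- array(FALSE, dim = c(20, 20, 10))
  m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(objectVolume(m, c(0.005, 0.005, 0.010)),
               1000 * 2.5e-7, tolerance = 1e-15)
  m6 <- array(FALSE, dim = c(4, 4, 4)); m6[1:6] <- TRUE
  expect_equal(objectVolume(m6, c(0.005, 0.005, 0.010)), 1.5e-6,
               tolerance = 1e-15)
})

test_that("Feret diameters match analytic geometry", {
  h <- 0.02
  # axis-aligned discrete cylinder, L = 1, r = 0.1 (built directly)
  dm <- c(24L, 24L, 60L)
  m <- array(FALSE, dim = dm)
  for (k in 1:50) {
    zs <- (k - 0.5) * h
    for (i in 1:24) for (j in 1:24) {
      x <- (j - 0.5) * h - 0.24; y <- (i - 0.5) * h - 0.24
      if (x^2 + y^2 <= 0.1^2) m[i, j, k] <- TRUE
    }
  }
  fer <- feretDiameters(m, rep(h, 3))
  corr <- sqrt(3) * h
  # corner-to-corner diameter of a cylinder: sqrt(L^2 + (2r)^2)
  expect_lt(abs(fer[["feretMaxUm"]] - (sqrt(1 + 0.2^2) + corr)), 0.05)
  expect_lt(abs(fer[["feretMinUm"]] - (0.2 + corr)), 0.05)
  expect_lte(fer[["feretMinUm"]], fer[["feretMaxUm"]])
  # sphere: max ~ min ~ diameter
  gs <- makeCapsuleVolume(list(rbind(c(0.5, 0.5, 0.5), c(0.500001, 0.5, 0.5))),
                          r = 0.2, shape = c(50L, 50L, 50L))
  fs <- feretDiameters(voxels(gs$volume) == 1L, rep(0.02, 3))
  expect_lt(abs(fs[["feretMaxUm"]] - (0.4 + corr)), 0.06)
  expect_lt(abs(fs[["feretMinUm"]] - (0.4 + corr)), 0.06)
  # single voxel: both equal the mean voxel diagonal
  m1 <- array(FALSE, dim = c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  f1 <- feretDiameters(m1, c(0.005, 0.005, 0.010))
  diagc <- sqrt(sum(c(0.005, 0.005, 0.010)^2))
  expect_equal(unname(f1), c(diagc, diagc), tolerance = 1e-9)
})

test_that("Feret diameters honor physical units under anisotropy", {
  # the same physical capsule, in-plane vs along the anisotropic z axis
  gxy <- makeCapsuleVolume(list(rbind(c(0.3, 0.5, 0.4), c(1.3, 0.5, 0.4))),
                           r = 0.12, vs = c(0.02, 0.02, 0.04),
                           shape = c(50L, 90L, 22L))
  gz <- makeCapsuleVolume(list(rbind(c(0.5, 0.5, 0.3), c(0.5, 0.5, 1.3))),
                          r = 0.12, vs = c(0.02, 0.02, 0.04),
                          shape = c(50L, 50L, 42L))
  fxy <- feretDiameters(voxels(gxy$volume) == 1L, c(0.02, 0.02, 0.04))
  fz <- feretDiameters(voxels(gz$volume) == 1L, c(0.02, 0.02, 0.04))
  expect_lt(abs(fxy[["feretMaxUm"]] - fz[["feretMaxUm"]]) /
              fxy[["feretMaxUm"]], 0.05)
  # regression guard: in voxel units the z-aligned extent would be ~2x off
  fzBad <- feretDiameters(voxels(gz$volume) == 1L, c(0.02, 0.02, 0.02))
  expect_lt(fzBad[["feretMaxUm"]], 0.75 * fz[["feretMaxUm"]])
})

test_that("3D classification combines the element rule with sub-object count", {
  expect_equal(classify3D(list(nElements = 3, nJunctions = 0), 1), "isolated")
  expect_equal(classify3D(list(nElements = 7, nJunctions = 1), 1), "branched")
  expect_equal(classify3D(list(nElements = 3, nJunctions = 0), 2), "clustered")
  expect_equal(classify3D(list(nElements = 11, nJunctions = 2), 1), "clustered")
})

test_that("the volume report conserves abundance and coverage", {
  recs <- data.frame(
    phenotype = c("isolated", "isolated", "isolated", "clustered"),
    volumeUm3 = c(0.05, 0.08, 0.07, 0.6),
    feretMaxUm = c(0.8, 1.5, 2.6, 3.0))
  vr <- volumeReport(recs)
  expect_equal(unname(vr$abundance[["isolated"]]), 0.75)
  expect_equal(sum(vr$abundance), 1, tolerance = 1e-12)
  expect_equal(sum(vr$volumeCoverage), 1, tolerance = 1e-12)
  expect_equal(sum(vr$isolatedSizeVolumeFrac), 1, tolerance = 1e-12)
  expect_equal(vr$totalVolumeUm3, 0.8)
  one <- data.frame(phenotype = "isolated", volumeUm3 = 1, feretMaxUm = 1.2)
  v1 <- volumeReport(one)
  expect_equal(unname(v1$abundance[["isolated"]]), 1)
  expect_equal(unname(v1$volumeCoverage[["isolated"]]), 1)
  expect_error(volumeReport(data.frame()), "empty")
})

test_that("the full 3D pipeline classifies a mixed synthetic scene correctly", {
  r <- 0.18
  sphere <- function(c0) rbind(c0, c0 + c(1e-6, 0, 0))
  specs <- list(
    mitoSpec(rbind(c(0.4, 0.4, 0.4), c(1.6, 0.4, 0.4)), 0.12),       # isolated
    mitoSpec(rbind(c(0.4, 1.2, 0.4), c(1.0, 1.2, 0.4),
                   c(1.6, 1.2, 0.4)), 0.12,                          # branched
             branches = list(list(attach = 2L,
                                  centerline = rbind(c(1.0, 1.9, 0.4))))),
    mitoSpec(sphere(c(0.5, 2.2, 0.4)), r),                           # fused pair
    mitoSpec(sphere(c(0.5 + 1.8 * r, 2.2, 0.4)), r))
  gv <- generateVolume3D(specs[1:2], voxelSizeUm = rep(0.02, 3),
                         volumeShape = c(140L, 110L, 40L))
  gv2 <- generateVolume3D(specs[3:4], voxelSizeUm = rep(0.02, 3),
                          volumeShape = c(140L, 110L, 40L), fuse = TRUE)
  v <- voxels(gv$volume)
  v2 <- voxels(gv2$volume)
  v[v2 > 0] <- v2[v2 > 0] + 2L
  lv <- labelVolume(v, rep(0.02, 3))
  rep3 <- analyzeVolume3D(lv)
  recs <- records(rep3)
  expect_equal(nrow(recs), 3)
  expect_setequal(recs$phenotype, c("isolated", "branched", "clustered"))
  # volume additivity: entity volumes sum to the scene total exactly
  expect_equal(sum(recs$volumeUm3), objectVolume(v > 0, rep(0.02, 3)),
               tolerance = 1e-12)
  expect_true(all(recs$feretMinUm <= recs$feretMaxUm))
  # watershed conservation: sub-object volumes sum to their parents
  so <- rep3@subObjects
  for (id in unique(so$parentComponentId)) {
    expect_equal(sum(so$volumeUm3[so$parentComponentId == id]),
                 recs$volumeUm3[recs$componentId == id], tolerance = 1e-12)
  }
})
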
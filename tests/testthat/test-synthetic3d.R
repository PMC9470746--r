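test_that("digital capsule volume matches the analytic formula within 5%", {
  spec <- mitoSpec(rbind(c(0.4, 0.6, 0.6), c(1.4, 0.6, 0.6)), 0.2)
  gv <- generateVolume3D(list(spec), voxelSizeUm = c(0.02, 0.02, 0.02),
                         volumeShape = c(60L, 100L, 60L))
  tr <- gv$truth$objects
  analytic <- pi * 0.2^2 * 1 + 4 / 3 * pi * 0.2^3
  expect_equal(tr$trueVolumeUm3, analytic, tolerance = 1e-12)
  voxelVol <- tr$voxelCount * prod(c(0.02, 0.02, 0.02))
  expect_lt(abs(voxelVol - analytic) / analytic, 0.05)
})

test_that("voxelized volume error decreases monotonically under refinement", {
  # average the |relative error| over sub-voxel placements of the object so
  # that the measurement reflects convergence, not grid-alignment luck
  set.seed(11)
  shifts <- matrix(runif(15, 0, 0.04), ncol = 3)
  meanErr <- vapply(c(0.04, 0.02, 0.01), function(h) {
    mean(vapply(1:5, function(k) {
      s <- shifts[k, ]
      spec <- mitoSpec(rbind(c(0.4, 0.5, 0.5) + s, c(1.2, 0.5, 0.5) + s), 0.15)
      shp <- as.integer(ceiling(c(1.1, 1.8, 1.1) / h))
      gv <- generateVolume3D(list(spec), voxelSizeUm = rep(h, 3),
                             volumeShape = shp)
      abs(gv$truth$objects$voxelCount * h^3 - spec$trueVolumeUm3) /
        spec$trueVolumeUm3
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanErr) < 0))
})

test_that("fused spheres share a label while truth keeps two identities", {
  r <- 0.2
  c1 <- c(0.5, 0.5, 0.5); c2 <- c1 + c(1.8 * r, 0, 0)
  sphere <- function(c0) mitoSpec(rbind(c0, c0 + c(1e-6, 0, 0)), r)
  gv <- generateVolume3D(list(sphere(c1), sphere(c2)),
                         voxelSizeUm = c(0.02, 0.02, 0.02),
                         volumeShape = c(50L, 70L, 50L), fuse = TRUE)
  expect_equal(gv$truth$scene$nLabels, 1L)
  expect_equal(nrow(gv$truth$objects), 2L)
  # without fuse, overlapping specs are rejected
  expect_error(
    generateVolume3D(list(sphere(c1), sphere(c2)),
                     voxelSizeUm = c(0.02, 0.02, 0.02),
                     volumeShape = c(50L, 70L, 50L), fuse = FALSE),
    "fuse")
})

test_that("default voxel size mirrors the FIB-SEM acquisition grid", {
  expect_equal(formals(generateVolume3D)$voxelSizeUm,
               quote(c(0.005, 0.005, 0.010)))
})

test_that("specs outside the volume are rejected; generation is deterministic", {
  spec <- mitoSpec(rbind(c(0.1, 0.1, 0.1), c(3, 0.1, 0.1)), 0.15)
  expect_error(generateVolume3D(list(spec), voxelSizeUm = rep(0.02, 3),
                                volumeShape = c(30L, 30L, 30L)), "bounds")
  ok <- mitoSpec(rbind(c(0.3, 0.3, 0.3), c(0.8, 0.3, 0.3)), 0.1)
  a <- generateVolume3D(list(ok), voxelSizeUm = rep(0.02, 3),
                        volumeShape = c(30L, 60L, 30L))
  b <- generateVolume3D(list(ok), voxelSizeUm = rep(0.02, 3),
                        volumeShape = c(30L, 60L, 30L))
  expect_identical(voxels(a$volume), voxels(b$volume))
})

test_that("anisotropic rasterization is exact in physical units", {
  # same physical capsule on an anisotropic grid: volume within tolerance
  spec <- mitoSpec(rbind(c(0.4, 0.5, 0.5), c(1.2, 0.5, 0.5)), 0.15)
  gv <- generateVolume3D(list(spec), voxelSizeUm = c(0.02, 0.02, 0.04),
                         volumeShape = c(50L, 80L, 25L))
  voxelVol <- gv$truth$objects$voxelCount * prod(c(0.02, 0.02, 0.04))
  expect_lt(abs(voxelVol - spec$trueVolumeUm3) / spec$trueVolumeUm3, 0.06)
})
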
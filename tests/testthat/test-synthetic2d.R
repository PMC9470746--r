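test_that("tubule generator echoes requested geometry in its ground truth", {
  tb <- generateTubule2D(4.0, radiusUm = 0.15, calibrationUmPerPx = 0.1)
  labs <- mitomorph:::.cc_label(as.vector(pixels(tb$mask)),
                                as.integer(dim(pixels(tb$mask))))
  expect_equal(max(labs), 1L)
  expect_equal(tb$truth$objects$trueLengthUm, 4.0)
  expect_equal(tb$truth$objects$nElements, 3L)
  # shortest confocal length bin is a valid object
  small <- generateTubule2D(0.5, radiusUm = 0.15)
  expect_equal(small$truth$objects$trueLengthUm, 0.5)
  expect_gt(sum(pixels(small$mask)), 0)
})

test_that("degenerate or out-of-bounds tubules are rejected", {
  expect_error(generateTubule2D(0.15, calibrationUmPerPx = 0.1),
               "smaller than 2 pixels")
  expect_error(generateTubule2D(0.25, radiusUm = 0.15), "diameter")
  expect_error(generateTubule2D(20, imageShape = c(64L, 64L)), "bounds")
})

test_that("branched generator computes element truth from topology", {
  yb <- generateBranched2D(2, c(1, 1)) # Y at trunk terminus
  expect_equal(unlist(yb$truth$objects[c("nEnds", "nJunctions", "nTubules")]),
               c(nEnds = 3L, nJunctions = 1L, nTubules = 3L))
  expect_equal(yb$truth$objects$nElements, 7L)

  # collinear single branch at the trunk end degenerates to a tubule
  cb <- generateBranched2D(2, 1, branchPositions = 1, branchAnglesDeg = 0)
  expect_equal(unlist(cb$truth$objects[c("nEnds", "nJunctions", "nTubules")]),
               c(nEnds = 2L, nJunctions = 0L, nTubules = 1L))

  hb <- generateBranched2D(3, c(1, 1), branchPositions = c(1 / 3, 2 / 3),
                           branchAnglesDeg = c(80, -80))
  expect_equal(hb$truth$objects$nElements, 11L)
  expect_equal(hb$truth$objects$truePhenotype, "clustered")
})

test_that("branch configurations that merge tube topology are rejected", {
  # two branches leaving the same point in the same direction
  expect_error(generateBranched2D(2, c(1, 1), branchAnglesDeg = c(30, 30)),
               "same direction|merge")
  # shallow branch running along the trunk
  expect_error(generateBranched2D(3, 1.5, branchPositions = 0.3,
                                  branchAnglesDeg = 4),
               "merge|shallow")
})

test_that("fluorescence rendering is seed-deterministic and invertible", {
  tb <- generateTubule2D(3, orientationDeg = 30)
  a <- renderFluorescence2D(tb$mask, psfSigmaUm = 0.15, poissonScale = 100,
                            gaussianSd = 0.02, background = 0.1, seed = 11)
  b <- renderFluorescence2D(tb$mask, psfSigmaUm = 0.15, poissonScale = 100,
                            gaussianSd = 0.02, background = 0.1, seed = 11)
  expect_identical(pixels(a), pixels(b))
  d <- renderFluorescence2D(tb$mask, psfSigmaUm = 0.15, poissonScale = 100,
                            gaussianSd = 0.02, background = 0.1, seed = 12)
  expect_false(identical(pixels(a), pixels(d)))
  # zero blur + zero noise: thresholding recovers the mask exactly
  clean <- renderFluorescence2D(tb$mask, psfSigmaUm = 0, poissonScale = 0,
                                gaussianSd = 0, background = 0.05, seed = 1)
  expect_identical(pixels(binarize(clean, minObjectAreaUm2 = 0)),
                   pixels(tb$mask))
  expect_error(renderFluorescence2D(tb$mask, psfSigmaUm = -1), "non-negative")
})

test_that("noise-free rendered tubule lengths are recovered on a 15-degree grid", {
  for (ang in seq(0, 90, by = 15)) {
    for (L in c(1, 4, 7)) {
      tb <- generateTubule2D(L, radiusUm = 0.15, orientationDeg = ang,
                             imageShape = c(256L, 256L))
      g <- skeletonize(tb$mask)[[1]]
      rec <- mitomorph:::componentLengthSmoothed(g, tipCorrection = TRUE)
      tol <- max(2 * 0.1, 0.05 * L)
      expect_lt(abs(rec - L), tol,
                label = sprintf("length error at %d deg, L=%g (got %.3f)",
                                ang, L, rec))
    }
  }
})
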
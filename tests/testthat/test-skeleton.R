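test_that("a straight bar skeletonizes to a path with two ends", {
  px <- matrix(FALSE, 20, 60)
  px[9:11, 11:50] <- TRUE
  g <- skeletonize(binaryMask(px, 0.1))
  expect_length(g, 1)
  s <- decomposeElements(g[[1]])
  expect_equal(s$nEnds, 2L)
  expect_equal(s$nJunctions, 0L)
  expect_equal(s$nTubules, 1L)
  expect_equal(s$nElements, 3L)
})

test_that("a rasterized Y yields exactly one merged junction", {
  for (ang in seq(0, 165, by = 15)) {
    yb <- generateBranched2D(2, c(1, 1), orientationDeg = ang)
    g <- skeletonize(yb$mask)
    expect_length(g, 1)
    s <- decomposeElements(g[[1]])
    expect_equal(s$nJunctions, 1L, label = paste("junctions at", ang, "deg"))
    expect_equal(s$nEnds, 3L, label = paste("ends at", ang, "deg"))
    expect_equal(s$nTubules, 3L, label = paste("tubules at", ang, "deg"))
  }
})

test_that("a solid disk collapses to a point-like skeleton", {
  px <- matrix(FALSE, 16, 16)
  for (i in 1:16) for (j in 1:16)
    if ((i - 8)^2 + (j - 8)^2 <= 2^2) px[i, j] <- TRUE
  g <- skeletonize(binaryMask(px, 0.1))
  expect_length(g, 1)
  s <- decomposeElements(g[[1]])
  expect_lte(s$nEnds, 2L)
  expect_equal(s$nJunctions, 0L)
})

test_that("empty masks give empty skeleton lists", {
  expect_length(skeletonize(binaryMask(matrix(FALSE, 8, 8), 0.1)), 0)
})

test_that("component length follows step geometry", {
  # 40-pixel straight skeleton: 39 axis steps of 0.1 um
  coords <- cbind(seq(0.05, by = 0.1, length.out = 40), 0.05)
  g <- skeletonGraph(coords, cbind(1:39, 2:40))
  expect_equal(componentLength(g), 3.9, tolerance = 1e-12)
  # 10 diagonal steps at 45 degrees
  coords <- cbind(seq(0, by = 0.1, length.out = 11),
                  seq(0, by = 0.1, length.out = 11))
  gd <- skeletonGraph(coords, cbind(1:10, 2:11))
  expect_equal(componentLength(gd), 10 * 0.1 * sqrt(2), tolerance = 1e-12)
  # single point
  gp <- skeletonGraph(matrix(c(0, 0), 1), matrix(integer(0), ncol = 2))
  expect_equal(componentLength(gp), 0)
})

test_that("element counts obey the Euler relation on acyclic fixtures", {
  fixtures <- list(
    generateTubule2D(3)$mask,
    generateBranched2D(2, c(1, 1))$mask,
    generateBranched2D(3, c(1, 1), branchPositions = c(1 / 3, 2 / 3),
                       branchAnglesDeg = c(80, -80))$mask,
    generateBranched2D(4, c(1, 1, 1), branchPositions = c(0.25, 0.5, 0.75),
                       branchAnglesDeg = c(80, -80, 80),
                       imageShape = c(200L, 200L))$mask)
  for (m in fixtures) {
    g <- skeletonize(m)[[1]]
    topo <- mitomorph:::skeletonTopology(g, 2)
    s <- decomposeElements(g)
    # condensed junction degree = number of incident non-internal chain ends
    ch <- topo$chains[!topo$chains$internal, , drop = FALSE]
    cl <- topo$clusterOf
    stubCount <- integer(s$nJunctions)
    for (i in seq_len(nrow(ch))) {
      for (side in c("A", "B")) {
        if (ch[[paste0("kind", side)]][i] == "cluster") {
          cid <- cl[ch[[paste0("end", side)]][i]]
          stubCount[cid] <- stubCount[cid] + 1L
        }
      }
    }
    expect_equal(s$nTubules,
                 sum(pmax(stubCount - 2L, 0L)) + s$nEnds - 1L,
                 label = "Euler relation")
  }
})

test_that("doubling the calibration doubles every reported length", {
  px <- pixels(generateBranched2D(2, c(1, 1))$mask)
  g1 <- skeletonize(binaryMask(px, 0.1))[[1]]
  g2 <- skeletonize(binaryMask(px, 0.2))[[1]]
  expect_equal(componentLength(g2), 2 * componentLength(g1), tolerance = 1e-12)
  expect_equal(decomposeElements(g2)$totalLengthUm,
               2 * decomposeElements(g1)$totalLengthUm, tolerance = 1e-12)
})

test_that("short terminal spurs are pruned, long ones are kept", {
  yb <- generateBranched2D(3, 0.3, branchPositions = 0.5,
                           branchAnglesDeg = 90)
  # a 0.3 um branch survives the default 0.1 um pruning
  s <- decomposeElements(skeletonize(yb$mask)[[1]])
  expect_equal(s$nJunctions, 1L)
  # with an aggressive threshold the branch is treated as a whisker
  s2 <- decomposeElements(skeletonize(yb$mask, pruneSpurUm = 0.5)[[1]])
  expect_equal(s2$nJunctions, 0L)
  expect_equal(s2$nElements, 3L)
})

test_that("3D skeleton of an axis-aligned tube is a simple path in physical units", {
  spec <- mitoSpec(rbind(c(0.3, 0.4, 0.4), c(1.5, 0.4, 0.4)), 0.12)
  gv <- generateVolume3D(list(spec), voxelSizeUm = c(0.02, 0.02, 0.04),
                         volumeShape = c(40L, 90L, 20L))
  g <- skeletonize(gv$volume)
  expect_length(g, 1)
  s <- decomposeElements(g[[1]])
  expect_equal(s$nEnds, 2L)
  expect_equal(s$nJunctions, 0L)
  # tip-corrected length approximates the tip-to-tip extent of the capsule
  # (centerline plus both hemispherical caps)
  tipToTip <- 1.2 + 2 * 0.12
  rec <- mitomorph:::componentLengthSmoothed(g[[1]], tipCorrection = TRUE)
  expect_lt(abs(rec - tipToTip) / tipToTip, 0.12)
})
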
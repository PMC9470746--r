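test_that("decomposition counts match junction pairing combinatorics", {
  expect_length(enumerateDecompositions(fixturePath()), 1)
  expect_length(enumerateDecompositions(fixtureY()), 4)
  expect_length(enumerateDecompositions(fixtureX()), 10)
})

test_that("matching enumeration equals the brute-force edge-partition oracle", {
  fixtures <- list(path = fixturePath(), Y = fixtureY(c(1, 1.5, 2)),
                   X = fixtureX(), H = fixtureH(), comb = fixtureComb())
  for (nm in names(fixtures)) {
    g <- fixtures[[nm]]
    impl <- enumerateDecompositions(g, tipCorrection = FALSE)
    oracle <- bruteForceDecompositions(g)
    expect_equal(canonDecomps(impl), canonDecomps(oracle),
                 label = paste("fixture", nm))
  }
})

test_that("Y with unit arms distributes mass 2/3 at 1 um and 1/3 at 2 um", {
  d <- lengthDistribution(list(fixtureY(c(1, 1, 1))))
  e <- binEdges(d); m <- binMass(d)
  b1 <- which(e[-length(e)] <= 1 & e[-1] > 1)
  b2 <- which(e[-length(e)] <= 2 & e[-1] > 2)
  expect_equal(m[b1], 2 / 3, tolerance = 1e-9)
  expect_equal(m[b2], 1 / 3, tolerance = 1e-9)
  expect_equal(sum(m), 1, tolerance = 1e-9)
})

test_that("junction-free populations reproduce the empirical length histogram", {
  g1 <- fixturePath(1); g3 <- fixturePath(3)
  d <- lengthDistribution(list(g1, g3))
  e <- binEdges(d); m <- binMass(d)
  expect_equal(m[which(e[-length(e)] <= 1 & e[-1] > 1)], 0.5)
  expect_equal(m[which(e[-length(e)] <= 3 & e[-1] > 3)], 0.5)
  expect_error(lengthDistribution(list()), "at least one")
})

test_that("length distributions always normalize, even when sampled", {
  # three degree-4 junctions in a row: 10^3 = 1000 combinations; cap at 50
  coords <- rbind(c(0, 0), c(1, 0), c(2, 0),
                  c(0, 1), c(0, -1), c(-1, 0),
                  c(1, 1), c(1, -1), c(2, 1), c(2, -1), c(3, 0))
  edges <- rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5), c(1, 6),
                 c(2, 7), c(2, 8), c(3, 9), c(3, 10), c(3, 11))
  g <- skeletonGraph(coords, edges)
  dec <- enumerateDecompositions(g, maxEnumeration = 50, seed = 9)
  expect_true(attr(dec, "sampled"))
  expect_equal(attr(dec, "nTotal"), 1000)
  d <- lengthDistribution(list(g, fixtureY()), maxEnumeration = 50, seed = 9)
  expect_equal(sum(binMass(d)), 1, tolerance = 1e-9)
  # and the sampling is seed-deterministic
  d2 <- lengthDistribution(list(g, fixtureY()), maxEnumeration = 50, seed = 9)
  expect_identical(binMass(d), binMass(d2))
})

test_that("connectivity follows J/(J+E) and its bounds", {
  tubules <- do.call(rbind, lapply(1:5, function(i)
    decomposeElements(fixturePath(i))))
  expect_equal(connectivity(tubules), 0)
  expect_equal(connectivity(decomposeElements(fixtureY())), 0.25)
  expect_equal(connectivity(decomposeElements(fixtureH())), 1 / 3,
               tolerance = 1e-12)
  # adding a junction to a population strictly increases connectivity
  popA <- rbind(tubules, decomposeElements(fixtureY()))
  popB <- rbind(tubules, decomposeElements(fixtureH()))
  expect_gt(connectivity(popB), connectivity(popA))
  # pure cycle: flagged connectivity 1
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- skeletonGraph(cbind(cos(th), sin(th)),
                        cbind(1:12, c(2:12, 1)))
  expect_warning(cc <- connectivity(decomposeElements(ring)), "cycle")
  expect_equal(as.numeric(cc), 1)
})

test_that("fractionLongerThan interpolates across the straddling bin", {
  d3 <- lengthDistribution(list(fixturePath(3)))
  expect_equal(fractionLongerThan(d3, 2), 1)
  uniform <- lengthDistributionFromMass(rep(1, 16), seq(0, 4, 0.25))
  expect_equal(fractionLongerThan(uniform, 2), 0.5)
  expect_equal(fractionLongerThan(uniform, 3.1), 0.225, tolerance = 1e-9)
})

test_that("a pure ring falls back to a flagged cyclic decomposition", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  ring <- skeletonGraph(cbind(cos(th), sin(th)), cbind(1:24, c(2:24, 1)))
  dec <- enumerateDecompositions(ring)
  expect_true(attr(dec, "cyclic"))
  expect_length(dec, 1)
})
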
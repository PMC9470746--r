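test_that("component classification follows the element-count rule", {
  expect_equal(classifyComponent(list(nElements = 3, nJunctions = 0)),
               "isolated")
  expect_equal(classifyComponent(list(nElements = 7, nJunctions = 1)),
               "branched") # Y: exactly 7 elements is NOT clustered
  expect_equal(classifyComponent(list(nElements = 11, nJunctions = 2)),
               "clustered")
  # raising the threshold never moves a component into the clustered class
  for (el in c(3, 7, 11, 25)) {
    p7 <- classifyComponent(list(nElements = el, nJunctions = 1), 7)
    p12 <- classifyComponent(list(nElements = el, nJunctions = 1), 12)
    expect_false(p7 != "clustered" && p12 == "clustered")
  }
})

test_that("area coverage fractions are conserved and isolate the long fraction", {
  recs <- data.frame(
    phenotype = c("clustered", "isolated", "isolated", "branched"),
    areaUm2 = c(2, 1, 0.5, 0.5),
    lengthUm = c(6, 2.5, 1, 1.5))
  cov <- areaCoverage(recs)
  expect_equal(sum(cov$areaFractions), 1, tolerance = 1e-12)
  expect_equal(unname(cov$areaFractions["clustered"]), 0.5)
  expect_equal(cov$totalAreaUm2, 4)
  # non-clustered area = 2; of it, the 2.5 um isolated component (area 1)
  expect_equal(cov$isolatedAreaFracLong, 0.5)
  allIso <- data.frame(phenotype = "isolated", areaUm2 = 1, lengthUm = 1)
  expect_equal(unname(areaCoverage(allIso)$areaFractions["isolated"]), 1)
  expect_error(areaCoverage(data.frame()), "empty")
})

test_that("cell phenotype follows the median-length thresholds", {
  edges <- seq(0, 10, 0.25)
  at <- function(um) {
    m <- numeric(length(edges) - 1)
    m[findInterval(um, edges)] <- 1
    lengthDistributionFromMass(m, edges)
  }
  expect_equal(classifyCell(at(0.5))$label, "short")
  expect_equal(classifyCell(at(1.5))$label, "intermediate")
  expect_equal(classifyCell(at(3))$label, "long")
  expect_equal(classifyCell(at(5))$label, "very long")
  # 50/50 split: the median tie resolves to the lower bin -> short
  m <- numeric(length(edges) - 1)
  m[findInterval(0.5, edges)] <- 0.5
  m[findInterval(5, edges)] <- 0.5
  split <- lengthDistributionFromMass(m, edges)
  cc <- classifyCell(split)
  expect_equal(cc$label, "short")
  expect_lt(cc$medianLengthUm, 1)
})

test_that("every record in a mixed synthetic scene gets exactly one phenotype", {
  px <- matrix(FALSE, 220, 220)
  place <- function(px, m, i0, j0) {
    d <- dim(m)
    px[i0:(i0 + d[1] - 1), j0:(j0 + d[2] - 1)] <-
      px[i0:(i0 + d[1] - 1), j0:(j0 + d[2] - 1)] | m
    px
  }
  px <- place(px, pixels(generateTubule2D(2, imageShape = c(60L, 60L))$mask), 5, 5)
  px <- place(px, pixels(generateBranched2D(2, c(1, 1),
                                            imageShape = c(70L, 70L))$mask), 5, 120)
  px <- place(px, pixels(generateBranched2D(3, c(1, 1),
                                            branchPositions = c(1 / 3, 2 / 3),
                                            branchAnglesDeg = c(80, -80),
                                            imageShape = c(90L, 90L))$mask), 110, 20)
  rep2 <- analyzeScene2D(binaryMask(px, 0.1))
  recs <- records(rep2)
  expect_equal(nrow(recs), 3)
  expect_true(all(recs$phenotype %in% c("isolated", "branched", "clustered")))
  expect_setequal(recs$phenotype, c("isolated", "branched", "clustered"))
  # per-phenotype areas sum exactly to the total foreground area
  expect_equal(sum(recs$areaUm2), sum(px) * 0.1^2, tolerance = 1e-12)
})
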
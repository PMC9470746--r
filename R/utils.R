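# Constructors and small shared helpers.

#' Construct a CalibratedImage
#' @param pixels numeric matrix (rows = y, columns = x)
#' @param calibration physical pixel size, um/px
#' @return a [CalibratedImage-class]
#' @export
calibratedImage <- function(pixels, calibration) {
  new("CalibratedImage", pixels = as.matrix(pixels),
      calibration = as.numeric(calibration))
}

#' Construct a BinaryMask
#' @param pixels logical matrix
#' @param calibration physical pixel size, um/px
#' @return a [BinaryMask-class]
#' @export
binaryMask <- function(pixels, calibration) {
  px <- as.matrix(pixels)
  storage.mode(px) <- "logical"
  new("BinaryMask", pixels = px, calibration = as.numeric(calibration))
}

#' Construct a LabelVolume
#' @param voxels integer 3D array, dim (y, x, z); 0 = background
#' @param voxelSize numeric length 3: voxel size along x, y, z in um
#' @return a [LabelVolume-class]
#' @export
labelVolume <- function(voxels, voxelSize) {
  v <- voxels
  storage.mode(v) <- "integer"
  vs <- as.numeric(voxelSize)
  names(vs) <- c("x", "y", "z")
  new("LabelVolume", voxels = v, voxelSize = vs)
}

#' Construct a SkeletonGraph from coordinates and an edge list
#'
#' Intended for building abstract network fixtures in code (physical
#' coordinates in micrometres); graphs extracted from rasters are produced
#' by [skeletonize()].
#'
#' @param coords numeric matrix, one row per node: columns x, y and
#'   optionally z (um). 2D coordinates get z = 0.
#' @param edges two-column integer matrix of node indices.
#' @param componentId integer id, default 1.
#' @param tipRadiusUm optional per-node boundary distance (um), default 0.
#' @return a [SkeletonGraph-class]
#' @export
skeletonGraph <- function(coords, edges, componentId = 1L, tipRadiusUm = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) == 2) coords <- cbind(coords, 0)
  n <- nrow(coords)
  edges <- matrix(as.integer(edges), ncol = 2)
  len <- if (nrow(edges)) sqrt(rowSums(
    (coords[edges[, 1], , drop = FALSE] - coords[edges[, 2], , drop = FALSE])^2
  )) else numeric(0)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  nodes <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      degree = deg,
                      tipRadiusUm = rep_len(tipRadiusUm, n),
                      pi = NA_integer_, pj = NA_integer_, pk = NA_integer_)
  new("SkeletonGraph", nodes = nodes,
      edges = data.frame(from = edges[, 1], to = edges[, 2], lengthUm = len),
      componentId = as.integer(componentId))
}

#' Construct a LengthDistribution
#' @param mass non-negative numeric, one entry per bin; normalized to sum 1
#' @param binEdges strictly increasing numeric bin edges (um)
#' @return a [LengthDistribution-class]
#' @export
lengthDistributionFromMass <- function(mass, binEdges) {
  s <- sum(mass)
  if (s <= 0) stop("total mass must be positive")
  new("LengthDistribution", binEdges = as.numeric(binEdges),
      mass = as.numeric(mass) / s)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so package functions never perturb user RNG flow.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Distance from points (px, py) to segment (a, b); all physical units.
pointSegDist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  l2 <- vx * vx + vy * vy
  if (l2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * vx + (py - ay) * vy) / l2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

# 3D variant for voxel grids.
pointSegDist3 <- function(px, py, pz, a, b) {
  v <- b - a
  l2 <- sum(v * v)
  if (l2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2 + (pz - a[3])^2))
  t <- ((px - a[1]) * v[1] + (py - a[2]) * v[2] + (pz - a[3]) * v[3]) / l2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (a[1] + t * v[1]))^2 + (py - (a[2] + t * v[2]))^2 +
       (pz - (a[3] + t * v[3]))^2)
}

# Shortest distance between two 2D segments (for overlap checking).
segSegDist <- function(p1, p2, q1, q2) {
  d <- c(
    pointSegDist(q1[1], q1[2], p1[1], p1[2], p2[1], p2[2]),
    pointSegDist(q2[1], q2[2], p1[1], p1[2], p2[1], p2[2]),
    pointSegDist(p1[1], p1[2], q1[1], q1[2], q2[1], q2[2]),
    pointSegDist(p2[1], p2[2], q1[1], q1[2], q2[1], q2[2])
  )
  if (segIntersect(p1, p2, q1, q2)) 0 else min(d)
}

segIntersect <- function(p1, p2, q1, q2) {
  cr <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  d1 <- cr(q1, q2, p1); d2 <- cr(q1, q2, p2)
  d3 <- cr(p1, p2, q1); d4 <- cr(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

polylineLength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

pkgProvenance <- function(parameters = list(), assumptions = character()) {
  list(
    package = "mitomorph",
    version = as.character(utils::packageVersion("mitomorph")),
    parameters = parameters,
    assumptions = assumptions
  )
}
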
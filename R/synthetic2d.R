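# Synthetic 2D scenes with exact ground truth. Objects are drawn as
# capsules (distance-to-centerline <= radius, computed in physical units),
# which gives rounded tips and an analytically known geometry.

# Rasterize a set of centerline segments as the union of capsules.
rasterizeSegments2D <- function(segments, radiusUm, calibrationUmPerPx,
                                imageShape) {
  nr <- imageShape[1]; nc <- imageShape[2]
  cal <- calibrationUmPerPx
  mask <- matrix(FALSE, nr, nc)
  for (s in segments) {
    lo <- pmin(s$a, s$b) - radiusUm - cal
    hi <- pmax(s$a, s$b) + radiusUm + cal
    j0 <- max(1L, floor(lo[1] / cal)); j1 <- min(nc, ceiling(hi[1] / cal) + 1L)
    i0 <- max(1L, floor(lo[2] / cal)); i1 <- min(nr, ceiling(hi[2] / cal) + 1L)
    if (j0 > j1 || i0 > i1) next
    xs <- (seq.int(j0, j1) - 0.5) * cal
    ys <- (seq.int(i0, i1) - 0.5) * cal
    PX <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    PY <- matrix(ys, length(ys), length(xs))
    d <- pointSegDist(PX, PY, s$a[1], s$a[2], s$b[1], s$b[2])
    mask[i0:i1, j0:j1] <- mask[i0:i1, j0:j1] | (d <= radiusUm)
  }
  mask
}

rotate2 <- function(pts, deg, center) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, `+`)
}

#' Generate a single synthetic 2D tubule
#'
#' Draws one mitochondrion-like tubule: a capsule whose tip-to-tip length is
#' `lengthUm` (a straight centerline of `lengthUm - 2*radiusUm` plus
#' rounded caps of radius `radiusUm`), so the recorded truth length is the
#' biological end-to-end length.
#'
#' @param lengthUm tip-to-tip length in um; must be at least two pixels and
#'   exceed the tube diameter.
#' @param radiusUm tube radius in um (default 0.15).
#' @param orientationDeg centerline orientation in degrees (default 0).
#' @param calibrationUmPerPx pixel size, um/px (default 0.1).
#' @param imageShape integer c(rows, cols) (default c(128, 128)).
#' @param centerUm optional c(x, y) position of the tubule center in um;
#'   defaults to the image center.
#' @return list with `mask` (a [BinaryMask-class]) and `truth` (per-object
#'   ground truth plus scene metadata).
#' @export
generateTubule2D <- function(lengthUm, radiusUm = 0.15, orientationDeg = 0,
                             calibrationUmPerPx = 0.1,
                             imageShape = c(128L, 128L), centerUm = NULL) {
  cal <- calibrationUmPerPx
  if (lengthUm < 2 * cal)
    stop("tubule length ", lengthUm, " um is smaller than 2 pixels (",
         2 * cal, " um)")
  if (lengthUm <= 2 * radiusUm)
    stop("tubule length must exceed the tube diameter (2 * radiusUm)")
  if (is.null(centerUm))
    centerUm <- c(imageShape[2], imageShape[1]) * cal / 2
  core <- (lengthUm - 2 * radiusUm) / 2
  u <- c(cos(orientationDeg * pi / 180), sin(orientationDeg * pi / 180))
  a <- centerUm - core * u
  b <- centerUm + core * u
  ext <- radiusUm + 2 * cal
  lo <- pmin(a, b) - ext; hi <- pmax(a, b) + ext
  fieldUm <- c(imageShape[2], imageShape[1]) * cal
  if (any(lo < 0) || any(hi > fieldUm))
    stop("object exceeds image bounds: extent [",
         paste(sprintf("%.3g", c(lo, hi)), collapse = ", "),
         "] um vs field ", paste(sprintf("%.3g", fieldUm), collapse = " x "),
         " um")
  mask <- rasterizeSegments2D(list(list(a = a, b = b)), radiusUm, cal,
                              imageShape)
  truth <- list(
    objects = data.frame(
      id = 1L, trueLengthUm = lengthUm, nEnds = 2L, nJunctions = 0L,
      nTubules = 1L, nElements = 3L, truePhenotype = "isolated",
      stringsAsFactors = FALSE),
    scene = list(calibrationUmPerPx = cal, imageShape = as.integer(imageShape),
                 radiusUm = radiusUm, orientationDeg = orientationDeg)
  )
  list(mask = binaryMask(mask, cal), truth = truth)
}

#' Generate a branched synthetic 2D object
#'
#' A trunk with one or more branches. Ground-truth element counts are
#' computed analytically from the centerline topology: ends are leaves,
#' junctions are attachment nodes of degree >= 3 (a collinear branch at a
#' trunk terminus makes a degree-2 node, which is not a junction), and
#' tubules are maximal junction-free paths. Configurations whose tubes
#' would merge away from their attachment points are rejected, since the
#' recorded topology would then be wrong.
#'
#' @param trunkUm trunk centerline length, um.
#' @param branchLengthsUm numeric vector of branch lengths, um (>= 1 branch).
#' @param branchPositions fractions along the trunk (0..1) where each branch
#'   attaches; default 1 (trunk terminus).
#' @param branchAnglesDeg branch direction relative to the trunk, degrees;
#'   default spreads branches at +/- 50 degrees.
#' @param orientationDeg rotation of the whole object, degrees.
#' @param radiusUm tube radius, um.
#' @param calibrationUmPerPx pixel size, um/px.
#' @param imageShape integer c(rows, cols).
#' @return list with `mask` ([BinaryMask-class]) and `truth`.
#' @export
generateBranched2D <- function(trunkUm, branchLengthsUm,
                               branchPositions = NULL, branchAnglesDeg = NULL,
                               orientationDeg = 0, radiusUm = 0.15,
                               calibrationUmPerPx = 0.1,
                               imageShape = c(160L, 160L)) {
  nb <- length(branchLengthsUm)
  if (nb < 1) stop("at least one branch is required")
  if (is.null(branchPositions)) branchPositions <- rep(1, nb)
  if (is.null(branchAnglesDeg))
    branchAnglesDeg <- seq(50, -50, length.out = max(nb, 2))[seq_len(nb)]
  if (length(branchPositions) != nb || length(branchAnglesDeg) != nb)
    stop("branchPositions and branchAnglesDeg must match branchLengthsUm")
  if (any(branchPositions < 0 | branchPositions > 1))
    stop("branch attachment positions must lie on the trunk (0..1)")
  cal <- calibrationUmPerPx

  # abstract node/edge topology in trunk coordinates (trunk along +x)
  t0 <- c(0, 0); t1 <- c(trunkUm, 0)
  attach <- cbind(branchPositions * trunkUm, 0)
  tips <- attach + cbind(cos(branchAnglesDeg * pi / 180) * branchLengthsUm,
                         sin(branchAnglesDeg * pi / 180) * branchLengthsUm)

  pts <- rbind(t0, t1, attach, tips)
  key <- apply(round(pts, 9), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  upts <- pts[!duplicated(key), , drop = FALSE]
  trunkNodes <- uid[c(1L, 2L, 2L + seq_len(nb))]  # t0, t1, attachments
  tipNodes <- uid[2L + nb + seq_len(nb)]
  # trunk split at sorted unique attachment fractions strictly inside (0,1)
  innerFrac <- sort(unique(branchPositions[branchPositions > 0 & branchPositions < 1]))
  chainFrac <- c(0, innerFrac, 1)
  chainPts <- cbind(chainFrac * trunkUm, 0)
  chainIds <- uid[match(apply(round(chainPts, 9), 1, paste, collapse = ","), key)]
  edges <- cbind(chainIds[-length(chainIds)], chainIds[-1])
  edges <- rbind(edges, cbind(uid[2L + seq_len(nb)], tipNodes))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges <- t(apply(edges, 1, sort))
  if (anyDuplicated(edges))
    stop("two segments leave the same node in the same direction; ",
         "topology would merge")

  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(upts))
  nEnds <- sum(deg == 1)
  nJunctions <- sum(deg >= 3)
  # tree: tubules = maximal junction-free paths = ends + junctions - 1
  nTubules <- nEnds + nJunctions - 1L
  nElements <- nEnds + nJunctions + nTubules

  # geometric segments and merge checks
  segs <- lapply(seq_len(nrow(edges)), function(i)
    list(a = upts[edges[i, 1], ], b = upts[edges[i, 2], ],
         n = edges[i, ]))
  minSep <- 2 * radiusUm + cal
  for (i in seq_along(segs)) for (j in seq_len(i - 1L)) {
    shared <- intersect(segs[[i]]$n, segs[[j]]$n)
    if (length(shared) == 0) {
      if (segSegDist(segs[[i]]$a, segs[[i]]$b, segs[[j]]$a, segs[[j]]$b) < minSep)
        stop("overlapping branches would merge the topology; ",
             "ground truth would be wrong")
    } else if (length(shared) == 1) {
      o <- upts[shared, ]
      fa <- if (all(segs[[i]]$a == o)) segs[[i]]$b else segs[[i]]$a
      fb <- if (all(segs[[j]]$a == o)) segs[[j]]$b else segs[[j]]$a
      va <- fa - o; vb <- fb - o
      la <- sqrt(sum(va^2)); lb <- sqrt(sum(vb^2))
      sinang <- abs(va[1] * vb[2] - va[2] * vb[1]) / (la * lb)
      cosang <- sum(va * vb) / (la * lb)
      if (cosang > 0.999999 && sinang < 1e-6)
        stop("two segments leave the same node in the same direction; ",
             "topology would merge")
      if (cosang > 0 && sinang * min(la, lb) < minSep)
        stop("branch angle too shallow: tubes merge beyond the junction")
    }
  }

  # place: rotate, then center the bounding box in the image
  allp <- do.call(rbind, lapply(segs, function(s) rbind(s$a, s$b)))
  allp <- rotate2(allp, orientationDeg, colMeans(allp))
  fieldUm <- c(imageShape[2], imageShape[1]) * cal
  shift <- fieldUm / 2 - (apply(allp, 2, min) + apply(allp, 2, max)) / 2
  allp <- sweep(allp, 2, shift, `+`)
  ext <- radiusUm + 2 * cal
  if (any(apply(allp, 2, min) < ext) || any(apply(allp, 2, max) > fieldUm - ext))
    stop("object exceeds image bounds")
  segsP <- lapply(seq_along(segs), function(i)
    list(a = allp[2 * i - 1, ], b = allp[2 * i, ]))
  mask <- rasterizeSegments2D(segsP, radiusUm, cal, imageShape)

  truth <- list(
    objects = data.frame(
      id = 1L, trueLengthUm = trunkUm + sum(branchLengthsUm),
      nEnds = nEnds, nJunctions = nJunctions, nTubules = nTubules,
      nElements = nElements,
      truePhenotype = if (nElements > 7L) "clustered"
                      else if (nJunctions >= 1L) "branched" else "isolated",
      stringsAsFactors = FALSE),
    scene = list(calibrationUmPerPx = cal, imageShape = as.integer(imageShape),
                 radiusUm = radiusUm, orientationDeg = orientationDeg)
  )
  list(mask = binaryMask(mask, cal), truth = truth)
}

#' Render a binary mask as a fluorescence-style image
#'
#' Forward model of a TMRM-like confocal appearance: the mask is convolved
#' with a Gaussian point-spread function, scaled Poisson shot noise is
#' applied (`Poisson(signal * scale) / scale`), then Gaussian read noise and
#' a constant background offset are added. Deterministic for a fixed seed;
#' with zero blur and zero noise, thresholding recovers the mask exactly.
#'
#' @param mask a [BinaryMask-class]
#' @param psfSigmaUm PSF standard deviation in um (0 disables blur)
#' @param poissonScale photon scaling for shot noise (0 disables)
#' @param gaussianSd additive Gaussian noise sd (0 disables)
#' @param background constant background level (signal amplitude is 1)
#' @param seed integer RNG seed
#' @return a [CalibratedImage-class]
#' @export
renderFluorescence2D <- function(mask, psfSigmaUm = 0.2, poissonScale = 200,
                                 gaussianSd = 0.01, background = 0.05,
                                 seed = 1L) {
  stopifnot(is(mask, "BinaryMask"))
  if (psfSigmaUm < 0 || poissonScale < 0 || gaussianSd < 0 || background < 0)
    stop("noise parameters must be non-negative")
  cal <- calibration(mask)
  img <- pixels(mask) * 1.0
  if (psfSigmaUm > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = psfSigmaUm / cal))
  img <- img + background
  withSeed(seed, {
    if (poissonScale > 0)
      img[] <- stats::rpois(length(img), pmax(img, 0) * poissonScale) /
        poissonScale
    if (gaussianSd > 0)
      img[] <- img + stats::rnorm(length(img), 0, gaussianSd)
  })
  calibratedImage(img, cal)
}
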
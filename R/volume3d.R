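# 3D arm of the pipeline: component labeling, watershed splitting of fused
# clusters, volumes, Feret diameters and phenotype classification.

#' Label connected components of a volume
#'
#' 26-connected labeling of the foreground of a binary or already-labeled
#' volume; background is preserved, every connected component receives a
#' unique positive label.
#'
#' @param volume a [LabelVolume-class]
#' @return a [LabelVolume-class] with connectivity-consistent labels
#' @export
labelComponents <- function(volume) {
  stopifnot(is(volume, "LabelVolume"))
  v <- voxels(volume)
  lab <- .cc_label(as.vector(v > 0L), as.integer(dim(v)))
  dim(lab) <- dim(v)
  labelVolume(lab, voxelSize(volume))
}

#' Split a fused component by anisotropic-aware watershed
#'
#' Seeds are the regional maxima of the Euclidean distance transform
#' (computed in physical units, so anisotropic voxels are honored); maxima
#' closer together than `seedMinDistanceUm` are merged into one seed. The
#' component is partitioned by flooding the negated distance transform from
#' the seeds; every foreground voxel is assigned to exactly one sub-object.
#' A component with a single seed is returned unsplit.
#'
#' @param mask logical 3D array (one connected component's foreground)
#' @param voxelSizeUm per-axis voxel size c(x, y, z), um
#' @param seedMinDistanceUm minimum physical separation between seeds, um
#'   (default 0.15, the mitochondrial radius scale)
#' @param hMinUm minimum basin prominence, um: two sub-objects remain split
#'   only if the distance-transform peak of each exceeds the saddle along
#'   their contact surface by at least this depth (default 0.05). This
#'   suppresses spurious splits along the flat ridge of a tube or at
#'   branch junctions while keeping genuine necks between fused organelles.
#' @return integer array of sub-object labels 1..k (0 = background)
#' @export
watershedSplit <- function(mask, voxelSizeUm, seedMinDistanceUm = 0.15,
                           hMinUm = 0.05) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  if (!any(mask)) stop("component is empty")
  vs <- as.numeric(voxelSizeUm)
  E <- maskEdt3D(mask, c(vs[2], vs[1], vs[3])) # spacing (y, x, z)
  seeds <- edtSeeds(E, mask, vs, seedMinDistanceUm)
  out <- .watershed_flood(as.vector(E), as.vector(seeds), as.vector(mask),
                          as.integer(dim(mask)))
  dim(out) <- dim(mask)
  out <- mergeShallowBasins(out, E, hMinUm)
  out
}

# Merge watershed basins whose separating saddle is within hMinUm of one of
# the two basin peaks (insufficient prominence).
mergeShallowBasins <- function(lab, E, hMinUm) {
  k <- max(lab)
  if (k <= 1 || hMinUm <= 0) return(lab)
  dm <- dim(lab)
  peak <- vapply(seq_len(k), function(i) max(E[lab == i]), numeric(1))
  # saddle height per adjacent label pair: max over contacts of min(E)
  offs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0),
               c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
               c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  pairKey <- integer(0); pairSad <- numeric(0)
  sadEnv <- new.env()
  for (o in offs) {
    i1 <- seq_len(dm[1]); i2 <- i1
    j1 <- seq_len(dm[2]); j2 <- j1
    k1 <- seq_len(dm[3]); k2 <- k1
    if (o[1] == 1) { i1 <- 1:(dm[1] - 1); i2 <- 2:dm[1] }
    if (o[2] == 1) { j1 <- 1:(dm[2] - 1); j2 <- 2:dm[2] }
    if (o[2] == -1) { j1 <- 2:dm[2]; j2 <- 1:(dm[2] - 1) }
    if (o[3] == 1) { k1 <- 1:(dm[3] - 1); k2 <- 2:dm[3] }
    if (o[3] == -1) { k1 <- 2:dm[3]; k2 <- 1:(dm[3] - 1) }
    a <- lab[i1, j1, k1]; b <- lab[i2, j2, k2]
    sel <- a > 0 & b > 0 & a != b
    if (!any(sel)) next
    lo <- pmin(a[sel], b[sel]); hi <- pmax(a[sel], b[sel])
    h <- pmin(E[i1, j1, k1][sel], E[i2, j2, k2][sel])
    keys <- paste(lo, hi)
    agg <- tapply(h, keys, max)
    for (nm in names(agg)) {
      cur <- mget(nm, envir = sadEnv, ifnotfound = -Inf)[[1]]
      assign(nm, max(cur, agg[[nm]]), envir = sadEnv)
    }
  }
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  repeat {
    merged <- FALSE
    for (nm in ls(sadEnv)) {
      ab <- as.integer(strsplit(nm, " ")[[1]])
      ra <- find(ab[1]); rb <- find(ab[2])
      if (ra == rb) next
      sad <- get(nm, envir = sadEnv)
      if (min(peak[ra], peak[rb]) - sad < hMinUm) {
        parent[ra] <- rb
        peak[rb] <- max(peak[ra], peak[rb])
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  roots <- vapply(seq_len(k), find, integer(1))
  newId <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- newId[lab[lab > 0]]
  out
}

# Regional maxima of the EDT, merged by physical peak distance.
edtSeeds <- function(E, mask, vs, seedMinDistanceUm) {
  dm <- dim(E)
  pad <- array(-Inf, dm + 2L)
  pad[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- E
  isMax <- array(TRUE, dm)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    sh <- pad[(2 + di):(dm[1] + 1L + di),
              (2 + dj):(dm[2] + 1L + dj),
              (2 + dk):(dm[3] + 1L + dk), drop = FALSE]
    dim(sh) <- dm
    isMax <- isMax & (E >= sh - 1e-12)
  }
  isMax <- isMax & mask
  if (!any(isMax)) { # flat EDT cannot happen for non-empty mask, but guard
    isMax[which.max(E)] <- TRUE
  }
  # plateau components of maxima
  plat <- .cc_label(as.vector(isMax), as.integer(dm))
  dim(plat) <- dm
  k <- max(plat)
  # representative peak per plateau (highest EDT, first index)
  reps <- t(vapply(seq_len(k), function(id) {
    w <- which(plat == id)
    w <- w[which.max(E[w])]
    arrayInd(w, dm)[1, ]
  }, integer(3)))
  pxyz <- cbind((reps[, 2] - 0.5) * vs[1], (reps[, 1] - 0.5) * vs[2],
                (reps[, 3] - 0.5) * vs[3])
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (k > 1) {
    for (a in seq_len(k)) for (b in seq_len(a - 1L)) {
      if (sqrt(sum((pxyz[a, ] - pxyz[b, ])^2)) < seedMinDistanceUm) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  group <- match(roots, unique(roots))
  seeds <- array(0L, dm)
  seeds[plat > 0] <- group[plat[plat > 0]]
  seeds
}

#' Physical volume of an object
#'
#' Voxel count times the voxel volume (exact integer-times-constant
#' arithmetic).
#'
#' @param mask logical array (or anything `sum()`-able to a voxel count)
#' @param voxelSizeUm per-axis voxel size c(x, y, z), um
#' @return volume in um^3
#' @export
objectVolume <- function(mask, voxelSizeUm) {
  sum(mask) * prod(as.numeric(voxelSizeUm))
}

# Quasi-uniform unit directions (Fibonacci sphere).
fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Minimum and maximum Feret diameters of a 3D object
#'
#' The maximum Feret diameter is the largest pairwise distance between
#' surface voxel centers (physical units); the minimum is the smallest
#' object extent over `nOrientations` quasi-uniform directions on the
#' sphere. Both receive a surface correction of one mean voxel diagonal,
#' since voxel-center extents underestimate the physical surface extent.
#'
#' @param mask logical 3D array
#' @param voxelSizeUm per-axis voxel size c(x, y, z), um
#' @param nOrientations number of sampled directions (default 256)
#' @return named numeric: `feretMinUm`, `feretMaxUm`
#' @export
feretDiameters <- function(mask, voxelSizeUm, nOrientations = 256L) {
  stopifnot(length(dim(mask)) == 3, any(mask))
  vs <- as.numeric(voxelSizeUm)
  dm <- dim(mask)
  # surface voxels: foreground with a background 6-neighbor (or on border)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- mask
  surf <- array(FALSE, dm)
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    sh <- pad[(2 + o[1]):(dm[1] + 1L + o[1]),
              (2 + o[2]):(dm[2] + 1L + o[2]),
              (2 + o[3]):(dm[3] + 1L + o[3]), drop = FALSE]
    dim(sh) <- dm
    surf <- surf | (mask & !sh)
  }
  w <- which(surf, arr.ind = TRUE)
  P <- cbind((w[, 2] - 0.5) * vs[1], (w[, 1] - 0.5) * vs[2],
             (w[, 3] - 0.5) * vs[3])
  corr <- sqrt(sum(vs^2))
  dirs <- fibonacciDirections(nOrientations)
  proj <- P %*% t(dirs)
  ext <- apply(proj, 2, max) - apply(proj, 2, min)
  feretMin <- min(ext) + corr
  cand <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
  C <- P[cand, , drop = FALSE]
  d2max <- 0
  if (nrow(C) > 1) {
    D2 <- as.matrix(stats::dist(C))
    d2max <- max(D2)
  }
  feretMax <- max(d2max, max(ext)) + corr
  c(feretMinUm = feretMin, feretMaxUm = feretMax)
}

#' Classify a 3D component into isolated, branched or clustered
#'
#' Same rule family as the 2D classification, extended by the watershed
#' criterion: a component is clustered when its element count exceeds the
#' threshold or when watershed splitting finds two or more physically
#' distinct sub-objects; otherwise branched when it has a junction, else
#' isolated.
#'
#' @param summary element summary row from [decomposeElements()]
#' @param nSubObjects number of watershed sub-objects of the component
#' @param clusterElementThreshold element-count threshold (default 7)
#' @return one of "isolated", "branched", "clustered"
#' @export
classify3D <- function(summary, nSubObjects, clusterElementThreshold = 7) {
  if (summary$nElements > clusterElementThreshold || nSubObjects >= 2)
    "clustered"
  else if (summary$nJunctions >= 1) "branched"
  else "isolated"
}

#' Scene-level 3D volume report
#'
#' Per-phenotype abundance (fraction of entities) and volume coverage
#' (fraction of total volume), the size distribution of isolated forms by
#' maximum Feret diameter (< 1, 1-2, > 2 um, as fractions of the total
#' isolated volume) and the total mitochondrial volume.
#'
#' @param records data.frame with columns `phenotype`, `volumeUm3`,
#'   `feretMaxUm`
#' @return list with `abundance`, `volumeCoverage`, `isolatedSizeVolumeFrac`,
#'   `totalVolumeUm3`, `n`
#' @export
volumeReport <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("volume report of an empty record set is undefined")
  phen <- c("isolated", "branched", "clustered")
  n <- nrow(records)
  total <- sum(records$volumeUm3)
  abundance <- vapply(phen, function(p)
    sum(records$phenotype == p) / n, numeric(1))
  coverage <- vapply(phen, function(p)
    sum(records$volumeUm3[records$phenotype == p]) / total, numeric(1))
  iso <- records[records$phenotype == "isolated", , drop = FALSE]
  isoFrac <- c(`<1um` = NA_real_, `1-2um` = NA_real_, `>2um` = NA_real_)
  if (nrow(iso) > 0) {
    vt <- sum(iso$volumeUm3)
    isoFrac <- c(
      `<1um` = sum(iso$volumeUm3[iso$feretMaxUm < 1]) / vt,
      `1-2um` = sum(iso$volumeUm3[iso$feretMaxUm >= 1 & iso$feretMaxUm <= 2]) / vt,
      `>2um` = sum(iso$volumeUm3[iso$feretMaxUm > 2]) / vt)
  }
  list(abundance = abundance, volumeCoverage = coverage,
       isolatedSizeVolumeFrac = isoFrac, totalVolumeUm3 = total, n = n)
}
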
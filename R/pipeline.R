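# End-to-end orchestration of the 2D (confocal-style) and 3D
# (FIB-SEM-style) analyses. Both are deterministic given their inputs and
# seeds and embed a provenance block listing the assumptions in force.

#' Analyze a 2D scene end to end
#'
#' Runs the full confocal-style pipeline: binarization (skipped when a mask
#' is supplied), skeletonization, element decomposition, per-component
#' phenotype classification, the probabilistic length distribution,
#' network summary statistics and the cell phenotype.
#'
#' @param x a [CalibratedImage-class] (will be binarized) or a
#'   [BinaryMask-class]
#' @param thresholdMethod,fixedThreshold,minObjectAreaUm2 passed to
#'   [binarize()] when `x` is a grayscale image
#' @param pruneSpurUm spur-pruning threshold, um
#' @param mergeRadiusPx junction merge radius, px
#' @param clusterElementThreshold cluster rule threshold (default 7)
#' @param cellThresholdsUm cell phenotype thresholds, um (default 1, 2, 4)
#' @param binWidthUm length distribution bin width, um
#' @param maxEnumeration,seed decomposition enumeration controls
#' @return a [MorphReport2D-class]
#' @export
analyzeScene2D <- function(x, thresholdMethod = "otsu", fixedThreshold = NULL,
                           minObjectAreaUm2 = NULL, pruneSpurUm = 0.1,
                           mergeRadiusPx = 2, clusterElementThreshold = 7,
                           cellThresholdsUm = c(1, 2, 4), binWidthUm = 0.25,
                           maxEnumeration = 10000, seed = 1L) {
  thresholdUsed <- NA_real_
  if (is(x, "CalibratedImage")) {
    mask <- binarize(x, method = thresholdMethod,
                     fixedThreshold = fixedThreshold,
                     minObjectAreaUm2 = minObjectAreaUm2)
    thresholdUsed <- attr(mask, "thresholdUsed")
  } else if (is(x, "BinaryMask")) {
    mask <- x
  } else stop("x must be a CalibratedImage or BinaryMask")
  cal <- calibration(mask)
  px <- pixels(mask)
  if (!any(px)) stop("no foreground: nothing to analyze")
  labs <- .cc_label(as.vector(px), as.integer(dim(px)))
  areas <- tabulate(labs[labs > 0]) * cal^2
  graphs <- skeletonize(mask, pruneSpurUm = pruneSpurUm)
  recs <- do.call(rbind, lapply(graphs, function(g) {
    s <- decomposeElements(g, mergeRadiusPx = mergeRadiusPx)
    s$lengthUm <- componentLengthSmoothed(g, tipCorrection = TRUE,
                                          mergeRadiusPx = mergeRadiusPx)
    s$areaUm2 <- areas[s$componentId]
    s$phenotype <- classifyComponent(s, clusterElementThreshold)
    s
  }))
  dist <- lengthDistribution(graphs, binWidthUm = binWidthUm,
                             maxEnumeration = maxEnumeration, seed = seed,
                             mergeRadiusPx = mergeRadiusPx,
                             tipCorrection = TRUE)
  cov <- areaCoverage(recs)
  conn <- connectivity(recs)
  network <- list(
    meanElementsPerCluster = mean(recs$nElements),
    connectivity = as.numeric(conn),
    areaFractions = cov$areaFractions,
    isolatedAreaFracLong = cov$isolatedAreaFracLong,
    fractionLengthGt2um = fractionLongerThan(dist, 2),
    nComponents = nrow(recs))
  cell <- classifyCell(dist, cellThresholdsUm)
  prov <- pkgProvenance(
    parameters = list(
      calibrationUmPerPx = cal, thresholdMethod = thresholdMethod,
      thresholdUsed = thresholdUsed, minObjectAreaUm2 = minObjectAreaUm2,
      pruneSpurUm = pruneSpurUm, mergeRadiusPx = mergeRadiusPx,
      clusterElementThreshold = clusterElementThreshold,
      cellThresholdsUm = cellThresholdsUm, binWidthUm = binWidthUm,
      maxEnumeration = maxEnumeration, seed = seed),
    assumptions = c(
      "threshold method and speck-removal area are analysis assumptions",
      "junction pairing model: stub matchings, equal weight per decomposition",
      "connectivity = junctions / (junctions + ends)",
      "cell phenotype thresholds on the median length are configurable defaults"))
  new("MorphReport2D", records = recs, distribution = dist, network = network,
      cellPhenotype = cell$label, provenance = prov)
}

#' Analyze a 3D volume end to end
#'
#' Runs the FIB-SEM-style pipeline: 26-connected component labeling, 3D
#' skeletonization and element decomposition per component, watershed
#' splitting of fused clusters, volumes and Feret diameters, phenotype
#' classification (element rule plus the multi-sub-object criterion) and
#' the scene-level volume report.
#'
#' @param volume a [LabelVolume-class] (binary or labeled)
#' @param seedMinDistanceUm watershed seed separation, um (default 0.15)
#' @param hMinUm minimum watershed basin prominence, um (default 0.05)
#' @param pruneSpurUm spur-pruning threshold, um
#' @param mergeRadiusPx junction merge radius, px (on the isotropic grid)
#' @param clusterElementThreshold cluster rule threshold (default 7)
#' @param nOrientations Feret diameter direction count
#' @return a [MorphReport3D-class]
#' @export
analyzeVolume3D <- function(volume, seedMinDistanceUm = 0.15, hMinUm = 0.05,
                            pruneSpurUm = 0.1, mergeRadiusPx = 2,
                            clusterElementThreshold = 7,
                            nOrientations = 256L) {
  stopifnot(is(volume, "LabelVolume"))
  lv <- labelComponents(volume)
  v <- voxels(lv)
  vs <- voxelSize(lv)
  if (!any(v > 0)) stop("no foreground: nothing to analyze")
  graphs <- skeletonize(lv, pruneSpurUm = pruneSpurUm)
  recs <- list(); subs <- list()
  for (g in graphs) {
    id <- g@componentId
    mask <- v == id
    s <- decomposeElements(g, mergeRadiusPx = mergeRadiusPx)
    split <- watershedSplit(mask, vs, seedMinDistanceUm = seedMinDistanceUm,
                            hMinUm = hMinUm)
    nSub <- length(setdiff(unique(as.vector(split)), 0L))
    fer <- feretDiameters(mask, vs, nOrientations = nOrientations)
    s$volumeUm3 <- objectVolume(mask, vs)
    s$feretMinUm <- fer[["feretMinUm"]]
    s$feretMaxUm <- fer[["feretMaxUm"]]
    s$nSubObjects <- nSub
    s$phenotype <- classify3D(s, nSub, clusterElementThreshold)
    recs[[length(recs) + 1L]] <- s
    for (sl in seq_len(nSub)) {
      sm <- split == sl
      sfer <- feretDiameters(sm, vs, nOrientations = nOrientations)
      subs[[length(subs) + 1L]] <- data.frame(
        parentComponentId = id, subObjectId = sl,
        volumeUm3 = objectVolume(sm, vs),
        feretMinUm = sfer[["feretMinUm"]], feretMaxUm = sfer[["feretMaxUm"]])
    }
  }
  recs <- do.call(rbind, recs)
  subs <- if (length(subs)) do.call(rbind, subs) else
    data.frame(parentComponentId = integer(0), subObjectId = integer(0),
               volumeUm3 = numeric(0), feretMinUm = numeric(0),
               feretMaxUm = numeric(0))
  summ <- volumeReport(recs)
  prov <- pkgProvenance(
    parameters = list(voxelSizeUm = as.list(vs),
                      seedMinDistanceUm = seedMinDistanceUm,
                      hMinUm = hMinUm,
                      pruneSpurUm = pruneSpurUm,
                      mergeRadiusPx = mergeRadiusPx,
                      clusterElementThreshold = clusterElementThreshold,
                      nOrientations = nOrientations),
    assumptions = c(
      "cluster rule: > threshold elements OR >= 2 watershed sub-objects",
      "watershed seeds from EDT maxima with physical minimum separation",
      "Feret surface correction: one mean voxel diagonal",
      "3D thinning on an isotropically resampled copy (min axis spacing)"))
  new("MorphReport3D", records = recs, subObjects = subs, summary = summ,
      provenance = prov)
}
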
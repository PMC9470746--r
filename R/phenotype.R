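# Phenotype classification for 2D components and whole cells.

#' Classify a network component by its element count
#'
#' A connected component with more than `clusterElementThreshold` elements
#' (ends + tubules + junctions) is a clustered form; otherwise it is
#' branched if it has at least one junction, and isolated if it has none.
#' With the default threshold of 7, an unbranched tubule (3 elements) is
#' isolated and a three-armed Y (7 elements) is still branched; 11 elements
#' is clustered.
#'
#' @param summary one-row data.frame (or list) with `nElements` and
#'   `nJunctions`, as returned by [decomposeElements()]
#' @param clusterElementThreshold element-count threshold (default 7)
#' @return one of "isolated", "branched", "clustered"
#' @export
classifyComponent <- function(summary, clusterElementThreshold = 7) {
  if (summary$nElements > clusterElementThreshold) "clustered"
  else if (summary$nJunctions >= 1) "branched"
  else "isolated"
}

#' Per-phenotype area coverage of a 2D scene
#'
#' Computes the fraction of total mitochondrial area covered by each
#' phenotype, the length distribution of non-clustered components, and the
#' fraction of non-clustered ("isolated mitochondrial") area contributed by
#' components longer than `longThresholdUm`.
#'
#' @param records data.frame with columns `phenotype`, `areaUm2` and
#'   `lengthUm` (component skeleton length)
#' @param longThresholdUm length threshold for the long-component area
#'   fraction (default 2)
#' @return list with `areaFractions` (named, sums to 1), `totalAreaUm2`,
#'   `nonClusteredLengthsUm`, `nonClusteredAreaFraction` and
#'   `isolatedAreaFracLong`
#' @export
areaCoverage <- function(records, longThresholdUm = 2) {
  if (is.null(records) || nrow(records) == 0)
    stop("area coverage of an empty record set is undefined")
  stopifnot(all(records$areaUm2 > 0))
  phen <- c("isolated", "branched", "clustered")
  total <- sum(records$areaUm2)
  fr <- vapply(phen, function(p)
    sum(records$areaUm2[records$phenotype == p]) / total, numeric(1))
  nonCl <- records[records$phenotype != "clustered", , drop = FALSE]
  isoLong <- if (nrow(nonCl) > 0)
    sum(nonCl$areaUm2[nonCl$lengthUm > longThresholdUm]) / sum(nonCl$areaUm2)
  else NA_real_
  list(areaFractions = fr,
       totalAreaUm2 = total,
       nonClusteredLengthsUm = nonCl$lengthUm,
       nonClusteredAreaFraction = sum(nonCl$areaUm2) / total,
       isolatedAreaFracLong = isoLong)
}

#' Classify a cell by its mitochondrial length distribution
#'
#' The cell statistic is the weighted median of the length distribution
#' (robust to a single large cluster): the smallest bin midpoint at which
#' the cumulative mass reaches 0.5 (ties resolve to the lower bin). The
#' label is assigned by three thresholds on the median length m:
#' short (m < t1), intermediate (t1 <= m < t2), long (t2 <= m < t3),
#' very long (m >= t3); defaults t = (1, 2, 4) um.
#'
#' @param dist a [LengthDistribution-class]
#' @param thresholdsUm increasing numeric of length 3, um (default 1, 2, 4)
#' @return list with `label` and `medianLengthUm`
#' @export
classifyCell <- function(dist, thresholdsUm = c(1, 2, 4)) {
  stopifnot(is(dist, "LengthDistribution"), length(thresholdsUm) == 3,
            all(diff(thresholdsUm) > 0))
  e <- binEdges(dist); m <- binMass(dist)
  mid <- (e[-1] + e[-length(e)]) / 2
  cm <- cumsum(m)
  med <- mid[which(cm >= 0.5 - 1e-12)[1]]
  label <- if (med < thresholdsUm[1]) "short"
  else if (med < thresholdsUm[2]) "intermediate"
  else if (med < thresholdsUm[3]) "long"
  else "very long"
  list(label = label, medianLengthUm = med)
}
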
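# The probabilistic structure interpreter: a connected skeleton network is
# ambiguous about which underlying mitochondria produced it, because at a
# junction two incident branches may either continue as one organelle or
# terminate. Every combination of stub pairings at the junctions defines one
# decomposition of the network into mitochondrion paths; the set of all
# decompositions induces a probability distribution over mitochondrial
# length.

# All partial matchings (including the empty one) of k stubs, as lists of
# index pairs. Counts follow the involution numbers: 1, 1, 2, 4, 10, 26...
enumerateMatchings <- function(k) {
  if (k <= 1) return(list(list()))
  rec <- function(idx) {
    if (length(idx) <= 1) return(list(list()))
    first <- idx[1]; rest <- idx[-1]
    out <- rec(rest) # first left unpaired
    for (j in seq_along(rest)) {
      sub <- rec(rest[-j])
      out <- c(out, lapply(sub, function(m) c(m, list(c(first, rest[j])))))
    }
    out
  }
  rec(seq_len(k))
}

countMatchings <- function(k) {
  if (k <= 1) return(1)
  countMatchings(k - 1) + (k - 1) * countMatchings(k - 2)
}

#' Enumerate path decompositions of a skeleton network
#'
#' At each junction of degree d, the d incident branch stubs are either
#' paired (two branches continue as one mitochondrion through the junction)
#' or left unpaired (a mitochondrion terminates there). Every combination of
#' pairings across all junctions yields one decomposition of the network
#' into simple mitochondrion paths. Combinations that would close a loop or
#' thread the same junction twice within one path are discarded (they do
#' not correspond to a partition into simple paths). If the combination
#' count exceeds `maxEnumeration`, decompositions are sampled uniformly with
#' the stated seed and the result is flagged via `attr(, "sampled")`.
#'
#' A component that is a pure cycle admits no simple-path decomposition; it
#' is returned as a single cyclic path, flagged via `attr(, "cyclic")`.
#'
#' @param graph a connected [SkeletonGraph-class]
#' @param maxEnumeration enumeration cap (default 10000)
#' @param seed RNG seed used only when sampling beyond the cap
#' @param mergeRadiusPx junction merge radius, as in [decomposeElements()]
#' @param tipCorrection add each path's boundary distance at skeleton leaf
#'   endpoints (default TRUE; abstract graphs carry zero tip radii)
#' @return list of decompositions, each a numeric vector of path lengths in
#'   um; attributes `nTotal`, `sampled`, `cyclic`
#' @export
enumerateDecompositions <- function(graph, maxEnumeration = 10000, seed = 1L,
                                    mergeRadiusPx = 2, tipCorrection = TRUE) {
  stopifnot(is(graph, "SkeletonGraph"))
  topo <- skeletonTopology(graph, mergeRadiusPx)
  decomposeTopology(topo, maxEnumeration = maxEnumeration, seed = seed,
                    tipCorrection = tipCorrection)
}

# Core enumeration on a precomputed topology (shared with the pipelines).
decomposeTopology <- function(topo, maxEnumeration = 10000, seed = 1L,
                              tipCorrection = TRUE) {
  ch <- topo$chains
  tube <- ch[!ch$internal, , drop = FALSE]
  tipOf <- function(tp) if (tipCorrection) tp else 0

  if (all(tube$cycle)) { # pure ring component
    out <- list(tube$lengthUm)
    attr(out, "nTotal") <- 1
    attr(out, "sampled") <- FALSE
    attr(out, "cyclic") <- TRUE
    return(out)
  }

  nc <- nrow(tube)
  # ports 2i-1 (endA) and 2i (endB) of chain i
  portCluster <- integer(2 * nc)
  clusterOf <- topo$clusterOf
  for (i in seq_len(nc)) {
    portCluster[2 * i - 1] <- if (tube$kindA[i] == "cluster")
      clusterOf[tube$endA[i]] else 0L
    portCluster[2 * i] <- if (tube$kindB[i] == "cluster")
      clusterOf[tube$endB[i]] else 0L
  }
  clusters <- sort(unique(portCluster[portCluster > 0]))
  stubs <- lapply(clusters, function(cl) which(portCluster == cl))
  counts <- vapply(stubs, function(s) countMatchings(length(s)), numeric(1))
  nTotal <- prod(counts)

  glue <- function(pairing) {
    # pairing: integer vector, pairing[port] = partner port or 0
    visited <- rep(FALSE, nc)
    paths <- list()
    startPorts <- which(portCluster == 0 | pairing == 0)
    for (p in startPorts) {
      i <- ceiling(p / 2)
      if (visited[i]) next
      lenSum <- 0
      clustersSeen <- integer(0)
      if (portCluster[p] > 0) clustersSeen <- portCluster[p]
      tip <- if (portCluster[p] == 0)
        tipOf(if (p %% 2 == 1) tube$tipA[i] else tube$tipB[i]) else 0
      cur <- p
      repeat {
        i <- ceiling(cur / 2)
        if (visited[i]) return(NULL) # revisit: not simple
        visited[i] <- TRUE
        lenSum <- lenSum + tube$lengthUm[i]
        other <- if (cur %% 2 == 1) cur + 1L else cur - 1L
        oc <- portCluster[other]
        if (oc > 0) {
          if (oc %in% clustersSeen) return(NULL) # junction threaded twice
          clustersSeen <- c(clustersSeen, oc)
          if (pairing[other] > 0) { cur <- pairing[other]; next }
          break # terminates at junction
        } else {
          tip <- tip + tipOf(if (other %% 2 == 1) tube$tipA[i] else tube$tipB[i])
          break # terminates at a leaf
        }
      }
      paths[[length(paths) + 1L]] <- lenSum + tip
    }
    if (!all(visited)) return(NULL) # leftover chains form closed loops
    unlist(paths)
  }

  buildPairing <- function(matchingPerCluster) {
    pairing <- integer(2 * nc)
    for (ci in seq_along(clusters)) {
      for (pr in matchingPerCluster[[ci]]) {
        a <- stubs[[ci]][pr[1]]; b <- stubs[[ci]][pr[2]]
        pairing[a] <- b; pairing[b] <- a
      }
    }
    pairing
  }

  sampled <- FALSE
  decomps <- list()
  if (length(clusters) == 0) {
    d <- glue(integer(2 * nc))
    if (!is.null(d)) decomps <- list(d)
  } else if (nTotal <= maxEnumeration) {
    matchSets <- lapply(stubs, function(s) enumerateMatchings(length(s)))
    idx <- rep(1L, length(clusters))
    sizes <- vapply(matchSets, length, integer(1))
    repeat {
      mpc <- lapply(seq_along(clusters), function(ci) matchSets[[ci]][[idx[ci]]])
      d <- glue(buildPairing(mpc))
      if (!is.null(d)) decomps[[length(decomps) + 1L]] <- d
      j <- 1L
      while (j <= length(idx)) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= sizes[j]) break
        idx[j] <- 1L; j <- j + 1L
      }
      if (j > length(idx)) break
    }
  } else {
    sampled <- TRUE
    matchSets <- lapply(stubs, function(s) enumerateMatchings(length(s)))
    sizes <- vapply(matchSets, length, integer(1))
    withSeed(seed, {
      for (r in seq_len(maxEnumeration)) {
        mpc <- lapply(seq_along(clusters), function(ci)
          matchSets[[ci]][[sample.int(sizes[ci], 1L)]])
        d <- glue(buildPairing(mpc))
        if (!is.null(d)) decomps[[length(decomps) + 1L]] <- d
      }
    })
  }

  cyclic <- FALSE
  if (length(decomps) == 0) {
    # every combination closes a loop (self-loop chains): fall back to one
    # decomposition treating each chain as a path, flagged
    decomps <- list(tube$lengthUm)
    cyclic <- TRUE
  }
  attr(decomps, "nTotal") <- nTotal
  attr(decomps, "sampled") <- sampled
  attr(decomps, "cyclic") <- cyclic
  decomps
}

#' Pooled length distribution over a set of network components
#'
#' Each connected component contributes all its path decompositions with
#' equal weight: a decomposition of a component with D decompositions has
#' weight 1/D, and within it every constituent path contributes 1/D as a
#' count. Counts are accumulated over all components and globally
#' normalized, so a component's total mass is proportional to its average
#' path count. With no junctions anywhere this reduces exactly to the
#' empirical histogram of component lengths.
#'
#' @param clusters list of [SkeletonGraph-class] (>= 1)
#' @param binWidthUm bin width in um (default 0.25)
#' @param maxUm minimum upper range of the binning (default 10; extended
#'   automatically if longer paths occur)
#' @param maxEnumeration,seed,mergeRadiusPx,tipCorrection passed to
#'   [enumerateDecompositions()]
#' @return a [LengthDistribution-class]
#' @export
lengthDistribution <- function(clusters, binWidthUm = 0.25, maxUm = 10,
                               maxEnumeration = 10000, seed = 1L,
                               mergeRadiusPx = 2, tipCorrection = TRUE) {
  if (length(clusters) == 0) stop("at least one cluster is required")
  lens <- numeric(0); wts <- numeric(0)
  for (g in clusters) {
    dec <- enumerateDecompositions(g, maxEnumeration = maxEnumeration,
                                   seed = seed, mergeRadiusPx = mergeRadiusPx,
                                   tipCorrection = tipCorrection)
    D <- length(dec)
    for (d in dec) {
      lens <- c(lens, d)
      wts <- c(wts, rep(1 / D, length(d)))
    }
  }
  hi <- max(maxUm, binWidthUm * ceiling(max(lens) / binWidthUm + 1e-9))
  edges <- seq(0, hi, by = binWidthUm)
  if (max(edges) < hi) edges <- c(edges, max(edges) + binWidthUm)
  bin <- pmin(floor(lens / binWidthUm + 1e-9) + 1L, length(edges) - 1L)
  mass <- numeric(length(edges) - 1L)
  for (i in seq_along(bin)) mass[bin[i]] <- mass[bin[i]] + wts[i]
  lengthDistributionFromMass(mass, edges)
}

#' Network connectivity statistic
#'
#' Ratio of junctions to junctions-plus-ends summed over all components:
#' 0 for a fully fragmented population (no junctions) and approaching 1 for
#' a hyperfused network. A population consisting only of pure cycles (no
#' ends, no junctions) is defined as connectivity 1 and flagged with a
#' warning.
#'
#' @param summaries data.frame of element summaries, as returned by
#'   [decomposeElements()] (rows rbind-ed over components)
#' @return connectivity in `[0, 1]`
#' @export
connectivity <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  J <- sum(summaries$nJunctions)
  E <- sum(summaries$nEnds)
  if (J + E == 0) {
    warning("population has no ends and no junctions (pure cycles); ",
            "connectivity defined as 1")
    return(structure(1, pureCycles = TRUE))
  }
  J / (J + E)
}

#' Fraction of mitochondrial length mass above a threshold
#'
#' Sums the probability mass of all bins entirely above `thresholdUm`, plus
#' the linear pro-rata share of the bin straddling the threshold.
#'
#' @param dist a [LengthDistribution-class]
#' @param thresholdUm threshold in um
#' @return fraction in `[0, 1]`
#' @export
fractionLongerThan <- function(dist, thresholdUm) {
  stopifnot(is(dist, "LengthDistribution"))
  e <- binEdges(dist); m <- binMass(dist)
  lo <- e[-length(e)]; hi <- e[-1]
  frac <- sum(m[lo >= thresholdUm])
  strad <- which(lo < thresholdUm & hi > thresholdUm)
  if (length(strad))
    frac <- frac + m[strad] * (hi[strad] - thresholdUm) / (hi[strad] - lo[strad])
  frac
}
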
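# Abstract skeleton fixtures (physical um coordinates) and independent
# oracles used across the test files.

# straight path: 2 leaves, no junction
fixturePath <- function(lenUm = 3) {
  skeletonGraph(rbind(c(0, 0), c(lenUm / 2, 0), c(lenUm, 0)),
                rbind(c(1, 2), c(2, 3)))
}

# Y: three arms meeting at one degree-3 node
fixtureY <- function(arms = c(1, 1, 1)) {
  th <- c(0, 2 * pi / 3, 4 * pi / 3)
  coords <- rbind(c(0, 0),
                  cbind(cos(th) * arms, sin(th) * arms))
  skeletonGraph(coords, cbind(1, 2:4))
}

# H: two degree-3 junctions joined by a bridge, four leaf arms
fixtureH <- function(arm = 1, bridge = 1) {
  coords <- rbind(
    c(0, 0), c(bridge, 0),                    # junctions 1, 2
    c(-arm / sqrt(2), arm / sqrt(2)), c(-arm / sqrt(2), -arm / sqrt(2)),
    c(bridge + arm / sqrt(2), arm / sqrt(2)),
    c(bridge + arm / sqrt(2), -arm / sqrt(2)))
  skeletonGraph(coords, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(2, 6)))
}

# X: four arms at one degree-4 node
fixtureX <- function(arm = 1) {
  coords <- rbind(c(0, 0), c(arm, 0), c(-arm, 0), c(0, arm), c(0, -arm))
  skeletonGraph(coords, cbind(1, 2:5))
}

# comb: three junctions along a backbone, each with one tooth
fixtureComb <- function() {
  coords <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(4, 0),
                  c(1, 1), c(2, 1), c(3, 1))
  skeletonGraph(coords, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                              c(2, 6), c(3, 7), c(4, 8)))
}

# ---------------------------------------------------------------------------
# Independent brute-force oracle for path decompositions: enumerate every
# set partition of the condensed chains and keep those whose blocks can be
# ordered into simple paths (joins only at junction clusters, no cluster
# visited twice). Completely independent of the matching-based
# implementation.

allPartitions <- function(items) {
  if (length(items) == 0) return(list(list()))
  first <- items[1]
  rest <- allPartitions(items[-1])
  out <- list()
  for (p in rest) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], first)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(first))
  }
  out
}

bruteForceDecompositions <- function(graph) {
  topo <- mitomorph:::skeletonTopology(graph, mergeRadiusPx = 2)
  ch <- topo$chains
  tube <- ch[!ch$internal & !ch$cycle, , drop = FALSE]
  cl <- topo$clusterOf
  tok <- function(node, kind, chain, side) {
    if (kind == "cluster") paste0("C", cl[node]) else paste0("L", chain, side)
  }
  epA <- vapply(seq_len(nrow(tube)), function(i)
    tok(tube$endA[i], tube$kindA[i], i, "a"), character(1))
  epB <- vapply(seq_len(nrow(tube)), function(i)
    tok(tube$endB[i], tube$kindB[i], i, "b"), character(1))
  isC <- function(t) startsWith(t, "C")

  blockIsSimplePath <- function(block) {
    dfs <- function(lastTok, seen, remaining) {
      if (length(remaining) == 0) return(TRUE)
      for (ci in remaining) {
        for (orient in 1:2) {
          u <- if (orient == 1) epA[ci] else epB[ci]
          v <- if (orient == 1) epB[ci] else epA[ci]
          if (u != lastTok) next
          if (isC(v) && v %in% seen) next
          s2 <- if (isC(v)) c(seen, v) else seen
          if (dfs(v, s2, setdiff(remaining, ci))) return(TRUE)
        }
      }
      FALSE
    }
    for (ci in block) {
      for (orient in 1:2) {
        u <- if (orient == 1) epA[ci] else epB[ci]
        v <- if (orient == 1) epB[ci] else epA[ci]
        if (isC(v) && isC(u) && u == v) next # self-loop start
        seen <- character(0)
        if (isC(u)) seen <- u
        if (isC(v)) { if (v %in% seen) next; seen <- c(seen, v) }
        if (dfs(v, seen, setdiff(block, ci))) return(TRUE)
      }
    }
    FALSE
  }

  parts <- allPartitions(seq_len(nrow(tube)))
  out <- list()
  for (p in parts) {
    if (all(vapply(p, blockIsSimplePath, logical(1)))) {
      out[[length(out) + 1L]] <-
        vapply(p, function(b) sum(tube$lengthUm[b]), numeric(1))
    }
  }
  out
}

# canonical form for comparing decomposition sets as multisets
canonDecomps <- function(dec) {
  sort(vapply(dec, function(d) paste(sprintf("%.6f", sort(d)), collapse = ","),
              character(1)))
}

# ---------------------------------------------------------------------------
# per-cell length distributions for the statistics tests: each cell is a
# histogram of n lengths drawn from a gamma law (shape 4, scale 0.5 um:
# mean 2 um, sd 1 um), optionally shifted
standardEdges <- seq(0, 10, by = 0.25)

makeCellDistribution <- function(n = 30, shift = 0, edges = standardEdges) {
  lens <- pmin(pmax(stats::rgamma(n, shape = 4, scale = 0.5) + shift, 0.01),
               max(edges) - 0.01)
  h <- graphics::hist(lens, breaks = edges, plot = FALSE)$counts
  lengthDistributionFromMass(h, edges)
}
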
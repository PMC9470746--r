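# Skeletonization and decomposition of binary objects into the element
# vocabulary of mitochondrial network analysis: ends (degree-1 skeleton
# nodes), junctions (merged clumps of degree->=3 nodes) and tubules
# (maximal junction-free paths).

# --- graph construction -----------------------------------------------------

# Build a spatial graph from integer raster points (one connected skeleton).
# pts: matrix with columns i (row/y), j (col/x), k (slice/z);
# spacing: physical um per step along (y, x, z);
# originUm: physical coordinate of the (0,0,0) voxel corner.
# Redundant diagonal edges (a diagonal step that can be decomposed into two
# less-diagonal steps through a third skeleton point) are removed so that
# rasterization does not create spurious triangles at corners.
buildGraphFromPoints <- function(pts, spacing, tipRadiusUm, componentId,
                                 originUm = c(0, 0, 0)) {
  n <- nrow(pts)
  K <- max(pts) + 2L
  key <- (pts[, 1] * K + pts[, 2]) * K + pts[, 3]
  lookup <- seq_len(n)
  names(lookup) <- as.character(key)

  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # positive half-space only, to enumerate each pair once
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]

  from <- integer(0); to <- integer(0); rank <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nk <- ((pts[, 1] + o[1]) * K + (pts[, 2] + o[2])) * K + (pts[, 3] + o[3])
    m <- lookup[as.character(nk)]
    hit <- which(!is.na(m))
    if (length(hit)) {
      from <- c(from, hit)
      to <- c(to, unname(m[hit]))
      rank <- c(rank, rep(sum(o != 0), length(hit)))
    }
  }

  if (length(from)) {
    adj <- vector("list", n)
    for (e in seq_along(from)) {
      adj[[from[e]]] <- c(adj[[from[e]]], to[e])
      adj[[to[e]]] <- c(adj[[to[e]]], from[e])
    }
    cheb <- function(a, b) max(abs(pts[a, ] - pts[b, ]))
    keep <- rep(TRUE, length(from))
    for (e in seq_along(from)) {
      if (rank[e] < 2) next
      a <- from[e]; b <- to[e]
      cand <- intersect(adj[[a]], adj[[b]])
      for (cc in cand) {
        if (cc == a || cc == b) next
        ra <- sum(pts[a, ] != pts[cc, ]); rb <- sum(pts[b, ] != pts[cc, ])
        if (cheb(a, cc) == 1 && cheb(b, cc) == 1 && ra < rank[e] && rb < rank[e]) {
          keep[e] <- FALSE
          break
        }
      }
    }
    from <- from[keep]; to <- to[keep]
  }

  dvec <- cbind((pts[from, 1] - pts[to, 1]) * spacing[1],
                (pts[from, 2] - pts[to, 2]) * spacing[2],
                (pts[from, 3] - pts[to, 3]) * spacing[3])
  lens <- if (length(from)) sqrt(rowSums(matrix(dvec, ncol = 3)^2)) else numeric(0)
  deg <- tabulate(c(from, to), nbins = n)
  nodes <- data.frame(
    x = originUm[1] + (pts[, 2] - 0.5) * spacing[2],
    y = originUm[2] + (pts[, 1] - 0.5) * spacing[1],
    z = originUm[3] + (pts[, 3] - 0.5) * spacing[3],
    degree = deg, tipRadiusUm = tipRadiusUm,
    pi = pts[, 1], pj = pts[, 2], pk = pts[, 3])
  new("SkeletonGraph", nodes = nodes,
      edges = data.frame(from = from, to = to, lengthUm = lens),
      componentId = as.integer(componentId))
}

# Remove terminal chains shorter than pruneSpurUm that hang off a junction
# (medial-axis whiskers). Iterates until stable; never removes a whole
# component.
pruneSpurs <- function(graph, pruneSpurUm = 0.1) {
  nodes <- graph@nodes; edges <- graph@edges
  if (pruneSpurUm <= 0 || nrow(edges) == 0) return(graph)
  repeat {
    n <- nrow(nodes)
    deg <- tabulate(c(edges$from, edges$to), nbins = n)
    adj <- adjacencyList(n, edges)
    removed <- rep(FALSE, n)
    any_removed <- FALSE
    for (leaf in which(deg == 1)) {
      if (removed[leaf]) next
      chain <- leaf; cur <- leaf; prev <- 0L; len <- 0
      repeat {
        nb <- adj[[cur]]
        nxt <- nb$node[nb$node != prev & !removed[nb$node]]
        eid <- nb$edge[nb$node != prev & !removed[nb$node]]
        if (length(nxt) != 1) break
        len <- len + edges$lengthUm[eid[1]]
        prev <- cur; cur <- nxt[1]
        if (deg[cur] != 2) break
        chain <- c(chain, cur)
      }
      if (deg[cur] >= 3 && len < pruneSpurUm && len > 0) {
        removed[chain] <- TRUE
        any_removed <- TRUE
      }
    }
    if (!any_removed) break
    keepN <- which(!removed)
    remap <- integer(n); remap[keepN] <- seq_along(keepN)
    keepE <- !removed[edges$from] & !removed[edges$to]
    edges <- edges[keepE, , drop = FALSE]
    edges$from <- remap[edges$from]; edges$to <- remap[edges$to]
    nodes <- nodes[keepN, , drop = FALSE]
    rownames(nodes) <- NULL; rownames(edges) <- NULL
  }
  deg <- tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
  nodes$degree <- deg
  new("SkeletonGraph", nodes = nodes, edges = edges,
      componentId = graph@componentId)
}

adjacencyList <- function(n, edges) {
  adj <- rep(list(list(node = integer(0), edge = integer(0))), n)
  for (e in seq_len(nrow(edges))) {
    a <- edges$from[e]; b <- edges$to[e]
    adj[[a]]$node <- c(adj[[a]]$node, b); adj[[a]]$edge <- c(adj[[a]]$edge, e)
    adj[[b]]$node <- c(adj[[b]]$node, a); adj[[b]]$edge <- c(adj[[b]]$edge, e)
  }
  adj
}

# --- skeletonize ------------------------------------------------------------

#' Skeletonize binary objects into spatial graphs
#'
#' Thins each connected foreground component to a single-point-wide medial
#' skeleton (8-connected in 2D, 26-connected in 3D; topology-preserving
#' sequential thinning) and converts it into a [SkeletonGraph-class] with
#' physical coordinates. 3D volumes are isotropically resampled to the
#' smallest axis spacing before thinning, since thinning assumes isotropy;
#' all reported lengths remain in physical micrometres. Skeleton nodes carry
#' their distance to the object boundary (`tipRadiusUm`) for optional
#' tip-length correction. Terminal spurs shorter than `pruneSpurUm` are
#' pruned before the graph is returned.
#'
#' @param x a [BinaryMask-class] or a [LabelVolume-class]
#' @param pruneSpurUm spur-pruning threshold in um (default 0.1)
#' @param ... unused
#' @return list of [SkeletonGraph-class], one per connected component (an
#'   empty mask gives an empty list)
#' @export
setGeneric("skeletonize", function(x, pruneSpurUm = 0.1, ...)
  standardGeneric("skeletonize"))

#' @rdname skeletonize
#' @export
setMethod("skeletonize", "BinaryMask", function(x, pruneSpurUm = 0.1, ...) {
  px <- pixels(x)
  cal <- calibration(x)
  if (!any(px)) return(list())
  dm <- dim(px)
  labs <- .cc_label(as.vector(px), as.integer(dm))
  thin <- .thin2d(as.vector(px), as.integer(dm))
  edt <- maskEdt2D(px, cal)
  dim(labs) <- dm; dim(thin) <- dm
  out <- list()
  for (id in sort(unique(labs[labs > 0]))) {
    sel <- which(thin & labs == id, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    pts <- cbind(sel[, 1], sel[, 2], 1L)
    tip <- edt[sel]
    g <- buildGraphFromPoints(pts, c(cal, cal, cal), tip, id)
    out[[length(out) + 1L]] <- pruneSpurs(g, pruneSpurUm)
  }
  out
})

#' @rdname skeletonize
#' @export
setMethod("skeletonize", "LabelVolume", function(x, pruneSpurUm = 0.1, ...) {
  v <- voxels(x)
  vs <- voxelSize(x) # (x, y, z)
  if (!any(v > 0)) return(list())
  vmin <- min(vs)
  out <- list()
  for (id in sort(unique(v[v > 0]))) {
    w <- which(v == id, arr.ind = TRUE)
    lo <- apply(w, 2, min); hi <- apply(w, 2, max)
    sub <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == id
    dim(sub) <- c(hi - lo + 1L)
    # nearest-neighbor resample to isotropic grid at vmin
    f <- c(vs["y"], vs["x"], vs["z"]) / vmin # per (i, j, k)
    nd <- pmax(1L, as.integer(round(dim(sub) * f)))
    ii <- pmin(dim(sub)[1], pmax(1L, floor((seq_len(nd[1]) - 0.5) / f[1]) + 1L))
    jj <- pmin(dim(sub)[2], pmax(1L, floor((seq_len(nd[2]) - 0.5) / f[2]) + 1L))
    kk <- pmin(dim(sub)[3], pmax(1L, floor((seq_len(nd[3]) - 0.5) / f[3]) + 1L))
    iso <- sub[ii, jj, kk, drop = FALSE]
    dim(iso) <- nd
    thin <- .thin3d(as.vector(iso), as.integer(nd))
    dim(thin) <- nd
    edt <- maskEdt3D(iso, c(vmin, vmin, vmin))
    sel <- which(thin, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    tip <- edt[sel]
    origin <- c((lo[2] - 1L) * vs["x"], (lo[1] - 1L) * vs["y"],
                (lo[3] - 1L) * vs["z"])
    g <- buildGraphFromPoints(sel, c(vmin, vmin, vmin), tip, id,
                              originUm = origin)
    out[[length(out) + 1L]] <- pruneSpurs(g, pruneSpurUm)
  }
  out
})

# Distance-to-background maps (physical units). The raster is padded with
# one background pixel per side, so objects touching the array border still
# have a finite boundary distance.
maskEdt2D <- function(px, cal) {
  dm <- dim(px)
  pad <- matrix(FALSE, dm[1] + 2L, dm[2] + 2L)
  pad[2:(dm[1] + 1L), 2:(dm[2] + 1L)] <- px
  d <- .edt_sq(as.vector(pad), as.integer(dim(pad)), c(cal, cal, cal))
  dim(d) <- dim(pad)
  sqrt(d[2:(dm[1] + 1L), 2:(dm[2] + 1L)])
}

maskEdt3D <- function(vx, spacingYXZ) {
  dm <- dim(vx)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- vx
  d <- .edt_sq(as.vector(pad), as.integer(dim(pad)), as.numeric(spacingYXZ))
  dim(d) <- dim(pad)
  sqrt(d[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L), drop = FALSE])
}

# --- topology ---------------------------------------------------------------

# Decompose a connected skeleton graph into chains between leaves and merged
# junction clusters. Junction nodes (degree >= 3) within a chessboard pixel
# radius of `mergeRadiusPx` of each other are merged into one junction, so
# that rasterization clumps do not inflate element counts.
# Returns chains with endpoint kinds, cluster count, leaf count and lengths.
skeletonTopology <- function(graph, mergeRadiusPx = 2) {
  nodes <- graph@nodes; edges <- graph@edges
  n <- nrow(nodes)
  if (n == 1L || nrow(edges) == 0) {
    # degenerate single-point component: a zero-length isolated mitochondrion
    return(list(
      chains = data.frame(endA = 1L, endB = 1L, kindA = "leaf", kindB = "leaf",
                          lengthUm = 0, rawLengthUm = 0,
                          tipA = nodes$tipRadiusUm[1],
                          tipB = nodes$tipRadiusUm[1], internal = FALSE,
                          cycle = FALSE, stringsAsFactors = FALSE),
      nEnds = 2L, nJunctions = 0L, nTubules = 1L,
      totalLengthUm = 0, clusterOf = rep(NA_integer_, n), degenerate = TRUE))
  }
  deg <- tabulate(c(edges$from, edges$to), nbins = n)
  adj <- adjacencyList(n, edges)
  jn <- which(deg >= 3)

  clusterOf <- rep(NA_integer_, n)
  if (length(jn)) {
    parent <- seq_along(jn)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (!all(is.na(nodes$pi[jn]))) {
      P <- cbind(nodes$pi[jn], nodes$pj[jn], nodes$pk[jn])
      for (a in seq_along(jn)) for (b in seq_len(a - 1L)) {
        if (max(abs(P[a, ] - P[b, ])) <= mergeRadiusPx) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    roots <- vapply(seq_along(jn), find, integer(1))
    clusterOf[jn] <- match(roots, unique(roots))
  }
  nClusters <- if (length(jn)) max(clusterOf[jn]) else 0L

  isJn <- !is.na(clusterOf)
  visitedE <- rep(FALSE, nrow(edges))
  chains <- list()
  walk <- function(start, eid) {
    # walk from `start` along edge `eid` until a leaf or junction node
    nb <- adj[[start]]
    nxt <- nb$node[nb$edge == eid]
    len <- edges$lengthUm[eid]
    visitedE[eid] <<- TRUE
    cur <- nxt
    seqNodes <- c(start, cur)
    interior <- 0L
    while (deg[cur] == 2 && !isJn[cur]) {
      nb <- adj[[cur]]
      pick <- which(!visitedE[nb$edge])
      if (length(pick) == 0) break # closed back
      e2 <- nb$edge[pick[1]]
      visitedE[e2] <<- TRUE
      len <- len + edges$lengthUm[e2]
      interior <- interior + 1L
      cur <- nb$node[nb$edge == e2][1]
      seqNodes <- c(seqNodes, cur)
    }
    list(endNode = cur, lengthUm = len, interior = interior,
         smoothUm = smoothChainLength(seqNodes))
  }
  coordsM <- as.matrix(nodes[, c("x", "y", "z")])
  # chord-resampled chain length (stride 3): removes the systematic
  # overestimate of raw 8/26-connected step sums for oblique lines while
  # following genuine curvature
  smoothChainLength <- function(idx) {
    if (length(idx) < 2) return(0)
    pick <- unique(c(seq(1L, length(idx), by = 3L), length(idx)))
    polylineLength(coordsM[idx[pick], , drop = FALSE])
  }
  starts <- which(deg == 1 | isJn)
  for (s in starts) {
    for (eid in adj[[s]]$edge) {
      if (visitedE[eid]) next
      res <- walk(s, eid)
      a <- s; b <- res$endNode
      kindA <- if (isJn[a]) "cluster" else "leaf"
      kindB <- if (isJn[b]) "cluster" else "leaf"
      # a short connector between two merged junction pixels is part of the
      # junction clump, not a tubule; a long same-cluster chain is a genuine
      # self-loop and stays a tubule
      internal <- kindA == "cluster" && kindB == "cluster" &&
        clusterOf[a] == clusterOf[b] && res$interior <= mergeRadiusPx
      chains[[length(chains) + 1L]] <- data.frame(
        endA = a, endB = b, kindA = kindA, kindB = kindB,
        lengthUm = res$smoothUm, rawLengthUm = res$lengthUm,
        tipA = if (kindA == "leaf") nodes$tipRadiusUm[a] else 0,
        tipB = if (kindB == "leaf") nodes$tipRadiusUm[b] else 0,
        internal = internal, cycle = FALSE, stringsAsFactors = FALSE)
    }
  }
  # leftover edges: pure cycles of degree-2 nodes
  while (any(!visitedE)) {
    eid <- which(!visitedE)[1]
    s <- edges$from[eid]
    res <- walk(s, eid)
    chains[[length(chains) + 1L]] <- data.frame(
      endA = s, endB = res$endNode, kindA = "cycle", kindB = "cycle",
      lengthUm = res$smoothUm, rawLengthUm = res$lengthUm, tipA = 0, tipB = 0,
      internal = FALSE, cycle = TRUE, stringsAsFactors = FALSE)
  }
  chains <- do.call(rbind, chains)
  nEnds <- sum(deg == 1)
  nTubules <- sum(!chains$internal)
  list(chains = chains, nEnds = as.integer(nEnds),
       nJunctions = as.integer(nClusters), nTubules = as.integer(nTubules),
       totalLengthUm = sum(edges$lengthUm), clusterOf = clusterOf,
       degenerate = FALSE)
}

#' Decompose a skeleton graph into ends, tubules and junctions
#'
#' Counts the elements of one connected skeleton component: ends are
#' degree-1 nodes, junctions are merged clumps of degree->=3 nodes (all
#' degree->=3 pixels within a chessboard radius of `mergeRadiusPx` collapse
#' into a single junction), and tubules are maximal junction-free paths. An
#' unbranched tubule therefore has three elements: two ends and one tubule.
#' A single-point skeleton counts as a degenerate isolated mitochondrion
#' (two ends, one tubule, length 0).
#'
#' @param graph a [SkeletonGraph-class]
#' @param mergeRadiusPx chessboard merge radius for junction clumps, in
#'   pixels (default 2)
#' @return one-row data.frame with `componentId`, `nEnds`, `nJunctions`,
#'   `nTubules`, `nElements` and `totalLengthUm`
#' @export
decomposeElements <- function(graph, mergeRadiusPx = 2) {
  stopifnot(is(graph, "SkeletonGraph"))
  topo <- skeletonTopology(graph, mergeRadiusPx)
  data.frame(
    componentId = graph@componentId,
    nEnds = topo$nEnds, nJunctions = topo$nJunctions,
    nTubules = topo$nTubules,
    nElements = topo$nEnds + topo$nJunctions + topo$nTubules,
    totalLengthUm = topo$totalLengthUm)
}

#' Total geodesic length of a skeleton component
#'
#' Sum of the physical edge lengths of the skeleton graph. With
#' `tipCorrection = TRUE`, the boundary distance stored at each degree-1
#' node is added, compensating for the retreat of the thinned skeleton from
#' rounded object tips (for a single-point skeleton the boundary distance is
#' added twice).
#'
#' @param graph a [SkeletonGraph-class]
#' @param tipCorrection extend the skeleton to the object boundary at each
#'   endpoint (default FALSE: pure geodesic length)
#' @return length in um
#' @export
componentLength <- function(graph, tipCorrection = FALSE) {
  stopifnot(is(graph, "SkeletonGraph"))
  len <- sum(graph@edges$lengthUm)
  if (tipCorrection) {
    if (nrow(graph@nodes) == 1L)
      len <- len + 2 * graph@nodes$tipRadiusUm[1]
    else
      len <- len + sum(graph@nodes$tipRadiusUm[graph@nodes$degree == 1])
  }
  len
}

# Component length from the chain decomposition: chord-resampled chain
# lengths (see smoothChainLength) plus, optionally, the boundary distance
# at each leaf. This is the pipeline's length estimate; componentLength()
# remains the raw geodesic edge sum.
componentLengthSmoothed <- function(graph, tipCorrection = TRUE,
                                    mergeRadiusPx = 2) {
  topo <- skeletonTopology(graph, mergeRadiusPx)
  len <- sum(topo$chains$lengthUm)
  if (tipCorrection)
    len <- len + sum(topo$chains$tipA) + sum(topo$chains$tipB)
  len
}
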
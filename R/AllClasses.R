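#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib mitomorph, .registration = TRUE
NULL

#' Calibrated 2D image
#'
#' A grayscale 2D raster together with its physical pixel size. This is the
#' unit of 2D analysis: every downstream length and area is reported in
#' micrometres by way of the calibration. Pixels are assumed square.
#'
#' @slot pixels numeric matrix of intensities (rows = y, columns = x).
#' @slot calibration physical pixel size in micrometres per pixel.
#' @export
setClass("CalibratedImage",
  representation(pixels = "matrix", calibration = "numeric"),
  validity = function(object) {
    if (length(object@calibration) != 1 || !is.finite(object@calibration) ||
        object@calibration <= 0)
      return("calibration must be a single positive number (um/px)")
    if (length(object@pixels) == 0)
      return("pixel raster is empty")
    TRUE
  }
)

#' Binary mitochondrial mask
#'
#' A thresholded 2D image: `TRUE` marks mitochondrial foreground. Retains
#' the calibration of its source image. Foreground connectivity is
#' 8-connected throughout the package.
#'
#' @slot pixels logical matrix.
#' @slot calibration physical pixel size in micrometres per pixel.
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", calibration = "numeric"),
  validity = function(object) {
    if (!is.logical(object@pixels))
      return("mask pixels must be logical")
    if (length(object@calibration) != 1 || object@calibration <= 0)
      return("calibration must be a single positive number (um/px)")
    TRUE
  }
)

#' Labeled 3D volume
#'
#' An integer 3D raster (0 = background, positive integers = object labels)
#' with per-axis physical voxel sizes, so anisotropic acquisitions (e.g.
#' finer in XY than in Z) are handled correctly. Array layout is (y, x, z).
#'
#' @slot voxels integer 3D array, dim (y, x, z).
#' @slot voxelSize named numeric of length 3: physical size of one voxel
#'   along x, y and z, in micrometres.
#' @export
setClass("LabelVolume",
  representation(voxels = "array", voxelSize = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3)
      return("voxels must be a 3D array (y, x, z)")
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
      return("voxelSize must be three positive numbers (x, y, z) in um")
    v <- object@voxels
    if (any(v < 0)) return("labels must be non-negative integers")
    TRUE
  }
)

#' Spatial skeleton graph of one connected component
#'
#' Nodes are skeleton pixels/voxels with physical coordinates in
#' micrometres; edges connect raster neighbors with their physical step
#' length. Degrees are stored per node; `tipRadiusUm` holds the distance
#' from the node to the object boundary (used for tip-length correction at
#' skeleton endpoints). Pixel indices (`pi`, `pj`, `pk`) are kept when the
#' graph came from a raster, so junction clumps can be merged by chessboard
#' distance; they are `NA` for abstract graphs built in code.
#'
#' @slot nodes data.frame with columns `x`, `y`, `z` (um), `degree`,
#'   `tipRadiusUm`, `pi`, `pj`, `pk`.
#' @slot edges data.frame with columns `from`, `to` (node row indices) and
#'   `lengthUm`.
#' @slot componentId integer component identifier within the source scene.
#' @export
setClass("SkeletonGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 componentId = "integer"),
  validity = function(object) {
    need <- c("x", "y", "z", "degree", "tipRadiusUm", "pi", "pj", "pk")
    if (!all(need %in% names(object@nodes)))
      return("nodes must have columns x, y, z, degree, tipRadiusUm, pi, pj, pk")
    if (nrow(object@edges) > 0) {
      if (!all(c("from", "to", "lengthUm") %in% names(object@edges)))
        return("edges must have columns from, to, lengthUm")
      if (any(object@edges$from < 1) || any(object@edges$to > nrow(object@nodes)))
        return("edge endpoints out of node range")
      if (any(object@edges$lengthUm < 0))
        return("edge lengths must be non-negative")
    }
    TRUE
  }
)

#' Binned length distribution
#'
#' Probability mass over mitochondrial length, on uniform bins (default
#' 0.25 um over [0, 10] um). The mass vector is non-negative and sums to 1.
#'
#' @slot binEdges strictly increasing numeric vector of bin edges (um).
#' @slot mass probability mass per bin; `length(mass) == length(binEdges)-1`.
#' @export
setClass("LengthDistribution",
  representation(binEdges = "numeric", mass = "numeric"),
  validity = function(object) {
    if (length(object@binEdges) < 2 || any(diff(object@binEdges) <= 0))
      return("binEdges must be strictly increasing, length >= 2")
    if (length(object@mass) != length(object@binEdges) - 1)
      return("mass must have one entry per bin")
    if (any(object@mass < -1e-12))
      return("mass must be non-negative")
    if (abs(sum(object@mass) - 1) > 1e-9)
      return("mass must sum to 1")
    TRUE
  }
)

#' 2D morphometry report
#'
#' Per-component records, the scene-level length distribution, network
#' summary statistics and the cell phenotype, plus a provenance block
#' (package version, parameters, assumption log).
#'
#' @slot records data.frame, one row per connected component.
#' @slot distribution [LengthDistribution-class] pooled over the scene.
#' @slot network list of scene-level network statistics.
#' @slot cellPhenotype character, one of short/intermediate/long/very long.
#' @slot provenance list.
#' @export
setClass("MorphReport2D",
  representation(records = "data.frame", distribution = "LengthDistribution",
                 network = "list", cellPhenotype = "character",
                 provenance = "list")
)

#' 3D morphometry report
#'
#' Entity-level records (one row per mitochondrial entity: isolated,
#' branched, or cluster), the watershed sub-objects of each entity, and the
#' volume/abundance summary.
#'
#' @slot records data.frame, one row per entity.
#' @slot subObjects data.frame, one row per watershed sub-object.
#' @slot summary list: abundance and volume-coverage fractions, totals.
#' @slot provenance list.
#' @export
setClass("MorphReport3D",
  representation(records = "data.frame", subObjects = "data.frame",
                 summary = "list", provenance = "list")
)
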
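# Accessor generics and show methods. Slot access outside the package goes
# through these.

#' Physical pixel size in micrometres per pixel
#' @param object a [CalibratedImage-class] or [BinaryMask-class]
#' @return numeric scalar (um/px)
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))

#' @rdname calibration
#' @export
setMethod("calibration", "CalibratedImage", function(object) object@calibration)

#' @rdname calibration
#' @export
setMethod("calibration", "BinaryMask", function(object) object@calibration)

#' Raster pixels of an image or mask
#' @param object a [CalibratedImage-class] or [BinaryMask-class]
#' @return matrix (rows = y, columns = x)
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "CalibratedImage", function(object) object@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(object) object@pixels)

#' Voxel raster of a labeled volume
#' @param object a [LabelVolume-class]
#' @return integer 3D array, dim (y, x, z)
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setMethod("voxels", "LabelVolume", function(object) object@voxels)

#' Per-axis voxel size in micrometres
#' @param object a [LabelVolume-class]
#' @return named numeric of length 3 (x, y, z)
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "LabelVolume", function(object) object@voxelSize)

#' Nodes of a skeleton graph
#' @param object a [SkeletonGraph-class]
#' @return data.frame of nodes (physical um coordinates, degree, tip radius)
#' @export
setGeneric("skeletonNodes", function(object) standardGeneric("skeletonNodes"))

#' @rdname skeletonNodes
#' @export
setMethod("skeletonNodes", "SkeletonGraph", function(object) object@nodes)

#' Edges of a skeleton graph
#' @param object a [SkeletonGraph-class]
#' @return data.frame of edges with physical step lengths (um)
#' @export
setGeneric("skeletonEdges", function(object) standardGeneric("skeletonEdges"))

#' @rdname skeletonEdges
#' @export
setMethod("skeletonEdges", "SkeletonGraph", function(object) object@edges)

#' Bin edges of a length distribution
#' @param object a [LengthDistribution-class]
#' @return numeric vector of bin edges (um)
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))

#' @rdname binEdges
#' @export
setMethod("binEdges", "LengthDistribution", function(object) object@binEdges)

#' Probability mass per bin
#' @param object a [LengthDistribution-class]
#' @return numeric vector summing to 1
#' @export
setGeneric("binMass", function(object) standardGeneric("binMass"))

#' @rdname binMass
#' @export
setMethod("binMass", "LengthDistribution", function(object) object@mass)

#' Per-component records of a report
#' @param object a [MorphReport2D-class] or [MorphReport3D-class]
#' @return data.frame
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "MorphReport2D", function(object) object@records)

#' @rdname records
#' @export
setMethod("records", "MorphReport3D", function(object) object@records)

#' Provenance block of a report
#' @param object a [MorphReport2D-class] or [MorphReport3D-class]
#' @return list with version, parameters and assumption log
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "MorphReport2D", function(object) object@provenance)

#' @rdname provenance
#' @export
setMethod("provenance", "MorphReport3D", function(object) object@provenance)

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CalibratedImage: %d x %d px at %.4g um/px (%.3g x %.3g um)\n",
              d[1], d[2], object@calibration,
              d[2] * object@calibration, d[1] * object@calibration))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryMask: %d x %d px at %.4g um/px, %d foreground px\n",
              d[1], d[2], object@calibration, sum(object@pixels)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  vs <- object@voxelSize
  cat(sprintf(
    "LabelVolume: %d x %d x %d voxels (y,x,z), voxel %.4g x %.4g x %.4g um, %d labels\n",
    d[1], d[2], d[3], vs[1], vs[2], vs[3],
    length(setdiff(unique(as.vector(object@voxels)), 0L))))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph (component %d): %d nodes, %d edges, %.3g um\n",
              object@componentId, nrow(object@nodes), nrow(object@edges),
              sum(object@edges$lengthUm)))
})

setMethod("show", "LengthDistribution", function(object) {
  mid <- (object@binEdges[-1] + object@binEdges[-length(object@binEdges)]) / 2
  cat(sprintf(
    "LengthDistribution: %d bins of %.3g um on [%.3g, %.3g] um, mean %.3g um\n",
    length(object@mass), diff(object@binEdges)[1], min(object@binEdges),
    max(object@binEdges), sum(mid * object@mass)))
})

setMethod("show", "MorphReport2D", function(object) {
  cat(sprintf("MorphReport2D: %d components, cell phenotype '%s'\n",
              nrow(object@records), object@cellPhenotype))
})

setMethod("show", "MorphReport3D", function(object) {
  cat(sprintf("MorphReport3D: %d entities, %d sub-objects, total %.4g um^3\n",
              nrow(object@records), nrow(object@subObjects),
              object@summary$totalVolumeUm3))
})
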
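# TIFF readers/writers and report export. Physical calibration travels in a
# JSON sidecar (`<basename>.meta.json`); readers additionally honor TIFF
# resolution tags on files produced elsewhere. All writers document their
# conventions: stacks are (y, x, z), coordinates and lengths are physical
# micrometres.

sidecarPath <- function(path) sub("\\.tiff?$", "", path, ignore.case = TRUE) |>
  paste0(".meta.json")

#' Write a calibrated image as TIFF (32-bit float) with a JSON sidecar
#'
#' Intensities are affinely mapped into `[0, 1]` for storage; the sidecar
#' records the offset/scale and the calibration, so reading restores both.
#'
#' @param image a [CalibratedImage-class]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
writeCalibratedImage <- function(image, path) {
  stopifnot(is(image, "CalibratedImage"))
  px <- pixels(image)
  off <- min(px); sc <- max(px) - off
  if (sc == 0) sc <- 1
  tiff::writeTIFF((px - off) / sc, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(kind = "CalibratedImage", calibration_um_per_px = calibration(image),
         intensity_offset = off, intensity_scale = sc),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated 2D image from TIFF
#'
#' Calibration precedence: an explicit `calibrationUmPerPx` argument wins
#' (with a warning if it conflicts with file metadata); otherwise TIFF
#' resolution tags are used when present; otherwise the JSON sidecar.
#' Multi-channel (e.g. RGB) images are rejected: the pipeline is
#' single-channel.
#'
#' @param path TIFF path
#' @param calibrationUmPerPx optional explicit pixel size, um/px
#' @return a [CalibratedImage-class]
#' @export
readCalibratedImage <- function(path, calibrationUmPerPx = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- tiff::readTIFF(path, info = TRUE, all = FALSE)
  if (length(dim(img)) == 3)
    stop("multi-channel image not supported (single channel required): ", path)
  fileCal <- NULL
  xres <- attr(img, "x.resolution")
  unit <- attr(img, "resolution.unit")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    perUm <- switch(ifelse(is.null(unit), "inch", unit),
                    inch = xres / 25400, cm = xres / 10000, xres)
    fileCal <- 1 / perUm
  }
  sp <- sidecarPath(path)
  off <- 0; sc <- 1
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (is.null(fileCal) && !is.null(meta$calibration_um_per_px))
      fileCal <- meta$calibration_um_per_px
    if (!is.null(meta$intensity_offset)) off <- meta$intensity_offset
    if (!is.null(meta$intensity_scale)) sc <- meta$intensity_scale
  }
  cal <- calibrationUmPerPx
  if (is.null(cal)) cal <- fileCal
  else if (!is.null(fileCal) && abs(cal - fileCal) > 1e-9 * fileCal)
    warning("calibration argument (", cal, ") overrides file metadata (",
            fileCal, ")")
  if (is.null(cal))
    stop("no calibration available for ", path,
         ": supply calibrationUmPerPx or provide metadata")
  px <- matrix(as.numeric(img), nrow = nrow(img)) # strip TIFF tag attributes
  calibratedImage(px * sc + off, cal)
}

#' Write a label volume as a multi-page TIFF with a JSON sidecar
#'
#' Pages are z-slices; labels are stored as 16-bit integers (<= 65535
#' labels). The sidecar records the per-axis voxel size.
#'
#' @param volume a [LabelVolume-class]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
writeLabelVolume <- function(volume, path) {
  stopifnot(is(volume, "LabelVolume"))
  v <- voxels(volume)
  if (max(v) > 65535L) stop("more than 65535 labels cannot be stored")
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  vs <- voxelSize(volume)
  jsonlite::write_json(
    list(kind = "LabelVolume", voxel_size_um = as.list(vs),
         axis_order = "(y, x, z); pages are z-slices",
         label_encoding = "stored_value * 65535"),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label volume from a multi-page TIFF
#'
#' @param path TIFF path
#' @param voxelSizeUm optional explicit per-axis voxel size c(x, y, z), um;
#'   overrides the sidecar (with a warning on conflict)
#' @return a [LabelVolume-class]
#' @export
readLabelVolume <- function(path, voxelSizeUm = NULL) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3)
    stop("multi-channel volume not supported (single channel required): ", path)
  v <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) v[, , k] <- as.integer(round(pages[[k]] * 65535))
  fileVs <- NULL
  sp <- sidecarPath(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size_um))
      fileVs <- unlist(meta$voxel_size_um)[c("x", "y", "z")]
  }
  vs <- voxelSizeUm
  if (is.null(vs)) vs <- fileVs
  else if (!is.null(fileVs) && any(abs(vs - fileVs) > 1e-12))
    warning("voxelSizeUm argument overrides file metadata")
  if (is.null(vs))
    stop("no voxel size available for ", path,
         ": supply voxelSizeUm or provide metadata")
  labelVolume(v, vs)
}

#' Write ground truth as a JSON sidecar
#'
#' Stores a generator truth block next to the image/volume it describes,
#' under `<basename>.truth.json`.
#'
#' @param truth truth list from a generator
#' @param path path of the TIFF the truth belongs to
#' @return sidecar path, invisibly
#' @export
writeSceneTruth <- function(truth, path) {
  tp <- sub("\\.tiff?$", "", path, ignore.case = TRUE) |> paste0(".truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(tp)
}

#' Export a skeleton graph as JSON
#'
#' Nodes carry physical um coordinates and degrees; edges carry physical
#' step lengths. Intended for external inspection.
#'
#' @param graph a [SkeletonGraph-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSkeletonGraph <- function(graph, path) {
  stopifnot(is(graph, "SkeletonGraph"))
  jsonlite::write_json(
    list(componentId = graph@componentId,
         nodes = graph@nodes[, c("x", "y", "z", "degree", "tipRadiusUm")],
         edges = graph@edges),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Write a 2D morphometry report to a directory
#'
#' Writes `components.csv` (one row per component), `distribution.csv`
#' (bin_low_um, bin_high_um, mass) and `summary.json` (network statistics,
#' cell phenotype and the provenance block).
#'
#' @param report a [MorphReport2D-class]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeReport2D <- function(report, dir) {
  stopifnot(is(report, "MorphReport2D"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@records, file.path(dir, "components.csv"),
                   row.names = FALSE)
  e <- binEdges(report@distribution)
  utils::write.csv(
    data.frame(bin_low_um = e[-length(e)], bin_high_um = e[-1],
               mass = binMass(report@distribution)),
    file.path(dir, "distribution.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(network = report@network, cellPhenotype = report@cellPhenotype,
         provenance = report@provenance),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a 3D morphometry report to a directory
#'
#' Writes `entities.csv`, `subobjects.csv` and `summary.json` (abundance,
#' volume coverage, totals, provenance).
#'
#' @param report a [MorphReport3D-class]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeReport3D <- function(report, dir) {
  stopifnot(is(report, "MorphReport3D"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@records, file.path(dir, "entities.csv"),
                   row.names = FALSE)
  utils::write.csv(report@subObjects, file.path(dir, "subobjects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = report@summary, provenance = report@provenance),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
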
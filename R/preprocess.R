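# Binarization of calibrated grayscale images into mitochondrial masks.

#' Binarize a calibrated image
#'
#' Thresholds a grayscale image into a mitochondrial foreground mask, then
#' removes connected foreground regions (8-connected) smaller than
#' `minObjectAreaUm2`. The default Otsu threshold is computed on the image's
#' own intensity range; a fixed threshold can be given instead. The
#' threshold actually used is attached as attribute `thresholdUsed`.
#'
#' @param image a [CalibratedImage-class]
#' @param method "otsu" (default) or "fixed"
#' @param fixedThreshold threshold value, required for `method = "fixed"`
#' @param minObjectAreaUm2 minimum object area kept, in um^2; default is the
#'   area of 4 pixels at the image calibration (shot-noise speck removal)
#' @return a [BinaryMask-class] with attribute `thresholdUsed`
#' @export
binarize <- function(image, method = c("otsu", "fixed"),
                     fixedThreshold = NULL, minObjectAreaUm2 = NULL) {
  stopifnot(is(image, "CalibratedImage"))
  method <- match.arg(method)
  px <- pixels(image)
  cal <- calibration(image)
  if (is.null(minObjectAreaUm2)) minObjectAreaUm2 <- 4 * cal^2
  rng <- range(px)
  if (method == "otsu") {
    if (diff(rng) == 0)
      stop("cannot Otsu-threshold a constant image")
    thr <- EBImage::otsu(px, range = rng, levels = 256L)
  } else {
    if (is.null(fixedThreshold))
      stop("method = \"fixed\" requires fixedThreshold")
    thr <- fixedThreshold
  }
  mask <- px > thr
  if (any(mask) && minObjectAreaUm2 > 0) {
    labs <- .cc_label(as.vector(mask), as.integer(dim(mask)))
    sizes <- tabulate(labs[labs > 0])
    drop <- which(sizes * cal^2 < minObjectAreaUm2)
    if (length(drop)) mask[matrix(labs %in% drop, nrow(mask))] <- FALSE
  }
  out <- binaryMask(mask, cal)
  attr(out, "thresholdUsed") <- as.numeric(thr)
  out
}
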
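#' Convert an RGB histology image to 8-bit grayscale
#'
#' Per-pixel unweighted channel mean (R+G+B)/3, rounded half-up and clipped to
#' 0--255 — the historical default of common histology measurement software.
#' An optional switch selects ITU-R BT.601 luminance weights instead.
#'
#' @param rgb a \linkS4class{RGBHistologyImage}, or a (height, width, 3) array
#'   on the 0--255 scale (then \code{pixelsPerMicron} is required).
#' @param weights "mean" (default) or "luminance".
#' @param pixelsPerMicron calibration, required for bare arrays.
#' @param sourceId provenance label for bare arrays.
#' @return a \linkS4class{CalibratedImage} with integer values 0--255.
#' @export
rgbToGray8 <- function(rgb, weights = c("mean", "luminance"),
                       pixelsPerMicron = NULL, sourceId = "") {
  weights <- match.arg(weights)
  if (is(rgb, "RGBHistologyImage")) {
    a <- rgb@pixels
    pixelsPerMicron <- rgb@pixelsPerMicron
    sourceId <- rgb@sourceId
  } else {
    a <- rgb
    if (is.null(pixelsPerMicron))
      stop("pixelsPerMicron is required when converting a bare array")
  }
  d <- dim(a)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected a 3-channel RGB raster")
  ch <- function(i) matrix(a[, , i], d[1], d[2])
  g <- if (weights == "mean") {
    (ch(1) + ch(2) + ch(3)) / 3
  } else {
    0.299 * ch(1) + 0.587 * ch(2) + 0.114 * ch(3)
  }
  g[] <- pmin(255, pmax(0, floor(g + 0.5)))   # half-up, clipped
  CalibratedImage(g, pixelsPerMicron, sourceId)
}

#' Binarize dark staining with a fixed threshold
#'
#' Von Kossa deposits are dark on a light counterstain, so foreground is
#' \code{intensity <= threshold} by default; set \code{polarity = "bright"}
#' for fluorescence-derived masks (\code{intensity > threshold}).
#'
#' @param gray a \linkS4class{CalibratedImage} on the 0--255 scale.
#' @param threshold integer in 0--255 (applied uniformly across conditions).
#' @param polarity "dark" (default) or "bright".
#' @return a \linkS4class{BinaryMask}; an empty result is valid, not an error.
#' @export
binarizeDark <- function(gray, threshold, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  stopifnot(is(gray, "CalibratedImage"))
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 255)
    stop("threshold must be a single integer in 0..255")
  m <- if (polarity == "dark") (gray@pixels <= threshold) else
    (gray@pixels > threshold)
  BinaryMask(m, gray@pixelsPerMicron)
}

#' Pooled-histogram Otsu threshold across conditions
#'
#' Computes Otsu's threshold on the pooled 256-bin histogram of all supplied
#' images, so that one value can be applied uniformly across conditions. Ties
#' in the between-class variance are broken at the midpoint of the maximizing
#' threshold set.
#'
#' @param images a \linkS4class{CalibratedImage} or a list of them.
#' @return integer threshold in 0--254; binarize with
#'   \code{binarizeDark(img, threshold)}.
#' @export
autoThreshold <- function(images) {
  if (is(images, "CalibratedImage")) images <- list(images)
  if (length(images) < 1L) stop("at least one image is required")
  counts <- integer(256)
  for (img in images) {
    stopifnot(is(img, "CalibratedImage"))
    counts <- counts + .hist256(img@pixels)
  }
  .otsu256(counts)
}

#' Integrated density and area fraction of a thresholded image
#'
#' Bookkeeping on a binary Von Kossa mask: integrated density is the sum of
#' binary-image intensities, i.e. 255 per foreground pixel; area fraction and
#' normalized density divide by the ROI pixel count (default: the full image).
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param roiPxCount positive integer ROI size in pixels; must be at least the
#'   foreground count. Defaults to the full image pixel count.
#' @param thresholdUsed integer threshold recorded for provenance (optional).
#' @param sourceId provenance label.
#' @return a \linkS4class{VKResult}
#' @export
vkMeasure <- function(mask, roiPxCount = NULL, thresholdUsed = NA_integer_,
                      sourceId = "") {
  stopifnot(is(mask, "BinaryMask"))
  nfg <- as.integer(sum(mask@mask))
  if (is.null(roiPxCount)) roiPxCount <- length(mask@mask)
  roiPxCount <- as.integer(roiPxCount)
  if (roiPxCount < 1L) stop("roiPxCount must be a positive integer")
  if (roiPxCount < nfg)
    stop("roiPxCount must be at least the foreground pixel count")
  new("VKResult",
      integratedDensity = 255 * nfg,
      areaFraction = nfg / roiPxCount,
      normalizedDensity = 255 * nfg / roiPxCount,
      thresholdUsed = as.integer(thresholdUsed),
      nForegroundPx = nfg, roiPxCount = roiPxCount,
      sourceId = as.character(sourceId))
}

#' One-call Von Kossa quantification of a grayscale or RGB image
#'
#' Converts RGB to 8-bit grayscale if needed, binarizes dark staining at the
#' given (or Otsu) threshold and measures integrated density.
#'
#' @param image a \linkS4class{CalibratedImage} or
#'   \linkS4class{RGBHistologyImage}.
#' @param threshold integer threshold, or "auto" for per-image Otsu. For the
#'   condition-uniform threshold of a multi-image study, compute one value
#'   with [autoThreshold()] over all images and pass it here.
#' @param roiPxCount optional ROI pixel count (default: full image).
#' @return a \linkS4class{VKResult}
#' @export
vkQuantify <- function(image, threshold = "auto", roiPxCount = NULL) {
  if (is(image, "RGBHistologyImage")) image <- rgbToGray8(image)
  stopifnot(is(image, "CalibratedImage"))
  thr <- if (identical(threshold, "auto")) autoThreshold(image) else
    as.integer(threshold)
  mask <- binarizeDark(image, thr)
  vkMeasure(mask, roiPxCount = roiPxCount, thresholdUsed = thr,
            sourceId = image@sourceId)
}
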
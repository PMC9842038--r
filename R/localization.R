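#' Median intensity z-projection of one channel
#'
#' Per-pixel median across z-slices of the channel with the requested role; a
#' median projection is robust to single-slice outliers while representing
#' the signal throughout the imaged volume. Even slice counts use the mean of
#' the two central order statistics.
#'
#' @param stack a \linkS4class{MultichannelStack}.
#' @param role "nuclei", "signal" or "other" — the channel to project.
#' @return a \linkS4class{CalibratedImage}
#' @export
medianProjection <- function(stack, role = c("signal", "nuclei", "other")) {
  stopifnot(is(stack, "MultichannelStack"))
  role <- match.arg(role)
  ci <- which(stack@channelRoles == role)
  if (length(ci) == 0L) stop("no channel carries role '", role, "'")
  ci <- ci[1]
  d <- dim(stack@voxels)
  if (d[1] == 1L) {
    proj <- matrix(stack@voxels[1, ci, , ], d[3], d[4])
  } else {
    arr <- array(stack@voxels[, ci, , ], dim = c(d[1], d[3], d[4]))
    proj <- apply(arr, c(2, 3), stats::median)
  }
  CalibratedImage(proj, stack@pixelsPerMicron,
                  sprintf("%s[%s-median]", stack@sourceId, role))
}

#' Segment nuclei from a DAPI image
#'
#' Otsu threshold on the DAPI channel (bright foreground), hole filling,
#' removal of connected components below \code{minAreaPx}, and 8-connected
#' labelling with labels ordered row-major by centroid. A constant image
#' yields 0 nuclei with a warning (supporting blank-control fixtures), not an
#' error. Nuclei touching the image border are retained.
#'
#' @param dapi a \linkS4class{CalibratedImage} of the nuclear counterstain.
#' @param minAreaPx positive integer: components smaller than this are
#'   treated as debris and dropped (default 50 px).
#' @return a \linkS4class{LabelMask}
#' @export
segmentNuclei <- function(dapi, minAreaPx = 50L) {
  stopifnot(is(dapi, "CalibratedImage"))
  minAreaPx <- as.integer(minAreaPx)
  if (minAreaPx < 1L) stop("minAreaPx must be a positive integer")
  px <- dapi@pixels
  if (all(px == px[1])) {
    warning("constant DAPI image: returning 0 nuclei")
    return(new("LabelMask",
               labels = matrix(0L, nrow(px), ncol(px)),
               nNuclei = 0L, pixelsPerMicron = dapi@pixelsPerMicron))
  }
  thr <- .otsu256(.hist256(px))
  bin <- (px > thr) + 0
  if (sum(bin) > 0) bin <- (as.matrix(EBImage::fillHull(bin)) > 0) + 0
  lab <- .label8(bin)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minAreaPx)
  lab[!(lab %in% keep)] <- 0L
  lab <- .orderLabelsRowMajor(lab)
  storage.mode(lab) <- "integer"
  new("LabelMask", labels = lab, nNuclei = max(lab),
      pixelsPerMicron = dapi@pixelsPerMicron)
}

#' Dilate segmented nuclei into the "cellular" pixel set
#'
#' Binary union of all nuclei dilated by an exact Euclidean disk of radius
#' \code{dilationPx}, capturing a small perinuclear area around each nucleus.
#'
#' @param labels a \linkS4class{LabelMask} (or \linkS4class{BinaryMask} of
#'   nuclei).
#' @param dilationPx nonnegative integer disk radius in px; 0 returns the
#'   undilated union.
#' @return a \linkS4class{BinaryMask} of cellular pixels.
#' @export
dilateNuclei <- function(labels, dilationPx) {
  dilationPx <- as.integer(dilationPx)
  if (dilationPx < 0L) stop("dilationPx must be >= 0")
  if (is(labels, "LabelMask")) {
    bin <- (labels@labels > 0) + 0
    ppm <- labels@pixelsPerMicron
  } else if (is(labels, "BinaryMask")) {
    bin <- labels@mask
    ppm <- labels@pixelsPerMicron
  } else stop("labels must be a LabelMask or BinaryMask")
  BinaryMask(.dilateDisk(bin, dilationPx), ppm)
}

#' Cell:ECM mean-intensity ratio
#'
#' Mean signal intensity over the cellular pixel set divided by the mean over
#' its complement (the "ECM" pixels); the two sets partition the image. The
#' ratio is invariant under global intensity scaling, which is what makes it
#' comparable across staining batches.
#'
#' @param signal a \linkS4class{CalibratedImage} of the signal of interest
#'   (e.g. an OPN median projection).
#' @param cellular a \linkS4class{BinaryMask} of cellular pixels, same shape.
#' @param nNuclei integer recorded for provenance.
#' @param dilationPx integer recorded for provenance.
#' @param sourceId provenance label; defaults to the signal image's.
#' @return a \linkS4class{LocalizationResult}. An empty or full cellular mask
#'   is a degenerate partition and errors; a zero ECM mean yields ratio
#'   \code{Inf} with a warning, never a silent drop.
#' @export
cellEcmRatio <- function(signal, cellular, nNuclei = NA_integer_,
                         dilationPx = NA_integer_,
                         sourceId = signal@sourceId) {
  stopifnot(is(signal, "CalibratedImage"), is(cellular, "BinaryMask"))
  if (!identical(dim(signal@pixels), dim(cellular@mask)))
    stop("signal and cellular mask must have the same shape")
  ncell <- sum(cellular@mask)
  ntot <- length(cellular@mask)
  if (ncell == 0 || ncell == ntot)
    stop("ratio undefined: degenerate partition (empty or full cellular mask)")
  inCell <- cellular@mask == 1
  cm <- mean(signal@pixels[inCell])
  em <- mean(signal@pixels[!inCell])
  ratio <- if (em == 0) {
    warning("ECM mean intensity is 0: reporting ratio as Inf")
    Inf
  } else cm / em
  new("LocalizationResult", cellMean = cm, ecmMean = em, ratio = ratio,
      nNuclei = as.integer(nNuclei), cellularFraction = ncell / ntot,
      dilationPx = as.integer(dilationPx), sourceId = as.character(sourceId))
}

#' Mean fluorescence intensity over an ROI
#'
#' @param signal a \linkS4class{CalibratedImage}.
#' @param roi optional \linkS4class{BinaryMask} restricting the measurement;
#'   default is the whole image. An empty ROI is an error.
#' @return scalar mean intensity.
#' @export
meanFluorescence <- function(signal, roi = NULL) {
  stopifnot(is(signal, "CalibratedImage"))
  if (is.null(roi)) return(mean(signal@pixels))
  stopifnot(is(roi, "BinaryMask"))
  if (!identical(dim(signal@pixels), dim(roi@mask)))
    stop("signal and roi must have the same shape")
  if (sum(roi@mask) == 0) stop("roi is empty")
  mean(signal@pixels[roi@mask == 1])
}

#' Full localization pipeline on a z-stack
#'
#' Median-projects the nuclei and signal channels, segments nuclei from the
#' DAPI projection, dilates them into the cellular set and measures the
#' cell:ECM mean-intensity ratio.
#'
#' @param stack a \linkS4class{MultichannelStack}.
#' @param dilationPx nonnegative integer perinuclear dilation radius
#'   (default 5 px, about 1.8 um at 2.73 px/um).
#' @param minAreaPx minimum nucleus area passed to [segmentNuclei()].
#' @return a \linkS4class{LocalizationResult}
#' @export
localizeStack <- function(stack, dilationPx = 5L, minAreaPx = 50L) {
  stopifnot(is(stack, "MultichannelStack"))
  dapi <- medianProjection(stack, "nuclei")
  nuc <- segmentNuclei(dapi, minAreaPx = minAreaPx)
  cellular <- dilateNuclei(nuc, dilationPx)
  sig <- medianProjection(stack, "signal")
  cellEcmRatio(sig, cellular, nNuclei = nuc@nNuclei,
               dilationPx = as.integer(dilationPx),
               sourceId = stack@sourceId)
}
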
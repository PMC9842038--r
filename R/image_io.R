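#' Construct a CalibratedImage
#'
#' @param pixels numeric matrix of intensities (nominally 0--255).
#' @param pixelsPerMicron positive calibration in pixels per micrometer. The
#'   calibration is always an explicit input; it is never inferred silently
#'   from file metadata.
#' @param sourceId free-text provenance label.
#' @return a \linkS4class{CalibratedImage}
#' @export
CalibratedImage <- function(pixels, pixelsPerMicron, sourceId = "") {
  new("CalibratedImage", pixels = pixels,
      pixelsPerMicron = as.numeric(pixelsPerMicron),
      sourceId = as.character(sourceId))
}

#' Construct a BinaryMask
#'
#' @param mask matrix (numeric or logical) with values in \{0, 1\}.
#' @param pixelsPerMicron positive calibration in pixels per micrometer.
#' @return a \linkS4class{BinaryMask}
#' @export
BinaryMask <- function(mask, pixelsPerMicron) {
  m <- mask + 0
  new("BinaryMask", mask = m, pixelsPerMicron = as.numeric(pixelsPerMicron))
}

#' Construct a MultichannelStack
#'
#' @param voxels numeric 4-d array ordered (z, channel, y, x).
#' @param channelRoles character vector of per-channel roles: exactly one
#'   "nuclei", exactly one "signal", the rest "other".
#' @param pixelsPerMicron positive in-plane calibration (px/um).
#' @param zStepUm positive axial step (um).
#' @param sourceId free-text provenance label.
#' @return a \linkS4class{MultichannelStack}
#' @export
MultichannelStack <- function(voxels, channelRoles, pixelsPerMicron, zStepUm,
                              sourceId = "") {
  new("MultichannelStack", voxels = voxels,
      channelRoles = as.character(channelRoles),
      pixelsPerMicron = as.numeric(pixelsPerMicron),
      zStepUm = as.numeric(zStepUm), sourceId = as.character(sourceId))
}

## Decode one raster file to a numeric array on the 0..255 (8-bit) or
## 0..65535 (16-bit) integer scale.
.readRaster <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    a <- png::readPNG(path)
    a <- a * 255
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE)
    a <- a + 0  # integer -> double, original bit-depth scale preserved
  } else {
    stop("unsupported image format (need TIFF or PNG): ", path)
  }
  a
}

#' Read a calibrated 2D image from TIFF or PNG
#'
#' Grayscale rasters return a \linkS4class{CalibratedImage} directly; RGB
#' rasters are passed through unconverted as a \linkS4class{RGBHistologyImage}
#' flagged for [rgbToGray8()]. Rasters with an alpha channel are rejected.
#'
#' @param path file path to a TIFF or PNG raster.
#' @param pixelsPerMicron positive calibration (px/um). May be omitted only
#'   when \code{useSidecar = TRUE} and a sidecar JSON written by
#'   [writeCalibratedImage()] sits next to the file.
#' @param sourceId provenance label; defaults to the file name.
#' @param useSidecar honor a \code{<path>.json} calibration sidecar when no
#'   explicit calibration is given.
#' @return a \linkS4class{CalibratedImage} or \linkS4class{RGBHistologyImage}
#' @export
readCalibratedImage <- function(path, pixelsPerMicron = NULL,
                                sourceId = basename(path),
                                useSidecar = FALSE) {
  if (is.null(pixelsPerMicron)) {
    side <- paste0(path, ".json")
    if (!useSidecar || !file.exists(side))
      stop("pixelsPerMicron is a required explicit input")
    pixelsPerMicron <- jsonlite::read_json(side)$pixels_per_micron
  }
  if (pixelsPerMicron <= 0) stop("pixelsPerMicron must be > 0")
  a <- .readRaster(path)
  if (length(dim(a)) == 2L || is.null(dim(a)))
    return(CalibratedImage(as.matrix(a), pixelsPerMicron, sourceId))
  if (length(dim(a)) == 3L && dim(a)[3] == 3L)
    return(new("RGBHistologyImage", pixels = a,
               pixelsPerMicron = as.numeric(pixelsPerMicron),
               sourceId = as.character(sourceId)))
  stop("unsupported channel layout in ", path,
       " (expected grayscale or 3-channel RGB)")
}

#' Write a calibrated image as TIFF with a calibration sidecar
#'
#' Pixel values are written losslessly at the requested integer bit depth; a
#' \code{<path>.json} sidecar records the calibration and provenance so the
#' image round-trips through [readCalibratedImage()].
#'
#' @param image a \linkS4class{CalibratedImage}. Values must be integers
#'   representable at the chosen bit depth (noise-carrying synthetic images
#'   are rounded).
#' @param path output TIFF path.
#' @param bitsPerSample 8 or 16.
#' @return \code{path}, invisibly.
#' @export
writeCalibratedImage <- function(image, path, bitsPerSample = 8L) {
  stopifnot(is(image, "CalibratedImage"), bitsPerSample %in% c(8L, 16L))
  maxv <- 2^bitsPerSample - 1
  px <- image@pixels
  px[] <- pmin(maxv, pmax(0, floor(px + 0.5)))
  tiff::writeTIFF(px / maxv, path, bits.per.sample = as.integer(bitsPerSample))
  jsonlite::write_json(
    list(pixels_per_micron = image@pixelsPerMicron,
         source_id = image@sourceId, bits_per_sample = bitsPerSample),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (foreground = 255)
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeBinaryMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  writeCalibratedImage(
    CalibratedImage(mask@mask * 255, mask@pixelsPerMicron, "mask"), path, 8L)
}

#' Read a multichannel z-stack from a multi-page TIFF
#'
#' The page count must equal z x channels under the declared page-order
#' convention. The default order is z-major: all channels of slice 1, then all
#' channels of slice 2, and so on.
#'
#' @param path multi-page TIFF path.
#' @param channelRoles character vector of roles, one per channel, in channel
#'   order: exactly one "nuclei" and one "signal".
#' @param pixelsPerMicron positive in-plane calibration (px/um).
#' @param zStepUm positive axial step (um).
#' @param pageOrder "z-major" (default) or "channel-major" (all slices of
#'   channel 1 first).
#' @param sourceId provenance label; defaults to the file name.
#' @return a \linkS4class{MultichannelStack}
#' @export
readMultichannelStack <- function(path, channelRoles, pixelsPerMicron,
                                  zStepUm, pageOrder = c("z-major",
                                                         "channel-major"),
                                  sourceId = basename(path)) {
  pageOrder <- match.arg(pageOrder)
  if (pixelsPerMicron <= 0) stop("pixelsPerMicron must be > 0")
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  nC <- length(channelRoles)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% nC != 0L)
    stop(sprintf("page count (%d) is not divisible by channel count (%d)",
                 length(pages), nC))
  nZ <- length(pages) %/% nC
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  vox <- array(0, dim = c(nZ, nC, H, W))
  for (p in seq_along(pages)) {
    if (pageOrder == "z-major") {
      z <- (p - 1L) %/% nC + 1L; ch <- (p - 1L) %% nC + 1L
    } else {
      ch <- (p - 1L) %/% nZ + 1L; z <- (p - 1L) %% nZ + 1L
    }
    vox[z, ch, , ] <- pages[[p]]
  }
  MultichannelStack(vox, channelRoles, pixelsPerMicron, zStepUm, sourceId)
}

#' Write a multichannel z-stack as a multi-page TIFF
#'
#' @param stack a \linkS4class{MultichannelStack}.
#' @param path output TIFF path.
#' @param bitsPerSample 8 or 16.
#' @param pageOrder page layout, as in [readMultichannelStack()].
#' @return \code{path}, invisibly.
#' @export
writeMultichannelStack <- function(stack, path, bitsPerSample = 8L,
                                   pageOrder = c("z-major", "channel-major")) {
  pageOrder <- match.arg(pageOrder)
  stopifnot(is(stack, "MultichannelStack"), bitsPerSample %in% c(8L, 16L))
  d <- dim(stack@voxels)
  maxv <- 2^bitsPerSample - 1
  pages <- list()
  idx <- if (pageOrder == "z-major") {
    expand.grid(ch = seq_len(d[2]), z = seq_len(d[1]))[, c("z", "ch")]
  } else {
    expand.grid(z = seq_len(d[1]), ch = seq_len(d[2]))[, c("z", "ch")]
  }
  for (k in seq_len(nrow(idx))) {
    sl <- matrix(stack@voxels[idx$z[k], idx$ch[k], , ], d[3], d[4])
    sl[] <- pmin(maxv, pmax(0, floor(sl + 0.5)))
    pages[[k]] <- sl / maxv
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitsPerSample))
  jsonlite::write_json(
    list(pixels_per_micron = stack@pixelsPerMicron, z_step_um = stack@zStepUm,
         channel_roles = as.list(stack@channelRoles), page_order = pageOrder,
         source_id = stack@sourceId),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert pixel lengths to micrometers
#'
#' @param lengthPx nonnegative length(s) in pixels.
#' @param pixelsPerMicron positive calibration (px/um).
#' @return \code{lengthPx / pixelsPerMicron}, in micrometers.
#' @examples
#' pxToUm(2.73, 2.73)   # 1 um
#' pxToUm(27.3, 2.73)   # 10 um
#' @export
pxToUm <- function(lengthPx, pixelsPerMicron) {
  if (any(pixelsPerMicron <= 0)) stop("pixelsPerMicron must be > 0")
  if (any(lengthPx < 0)) stop("lengths must be >= 0")
  lengthPx / pixelsPerMicron
}

#' Convert micrometer lengths to pixels
#'
#' @param lengthUm nonnegative length(s) in micrometers.
#' @param pixelsPerMicron positive calibration (px/um).
#' @return \code{lengthUm * pixelsPerMicron}, in pixels.
#' @export
umToPx <- function(lengthUm, pixelsPerMicron) {
  if (any(pixelsPerMicron <= 0)) stop("pixelsPerMicron must be > 0")
  if (any(lengthUm < 0)) stop("lengths must be >= 0")
  lengthUm * pixelsPerMicron
}
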
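#' Extract the pixel matrix of an image
#' @param x an image object
#' @return numeric matrix (or array for RGB images)
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Spatial calibration in pixels per micrometer
#' @param x a calibrated object
#' @return positive scalar (px/um)
#' @export
setGeneric("pixelsPerMicron", function(x) standardGeneric("pixelsPerMicron"))

#' Provenance label of an object
#' @param x an object carrying a source identifier
#' @return character scalar
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' Extract the 0/1 mask matrix
#' @param x a \linkS4class{BinaryMask}
#' @return numeric matrix of 0/1
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' Extract the integer label matrix
#' @param x a \linkS4class{LabelMask}
#' @return integer matrix (0 = background)
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' Number of segmented nuclei
#' @param x a \linkS4class{LabelMask} or \linkS4class{LocalizationResult}
#' @return integer count
#' @export
setGeneric("nNuclei", function(x) standardGeneric("nNuclei"))

#' @rdname pixels
#' @export
setMethod("pixels", "CalibratedImage", function(x) x@pixels)
#' @rdname pixels
#' @export
setMethod("pixels", "RGBHistologyImage", function(x) x@pixels)

#' @rdname pixelsPerMicron
#' @export
setMethod("pixelsPerMicron", "CalibratedImage", function(x) x@pixelsPerMicron)
#' @rdname pixelsPerMicron
#' @export
setMethod("pixelsPerMicron", "RGBHistologyImage", function(x) x@pixelsPerMicron)
#' @rdname pixelsPerMicron
#' @export
setMethod("pixelsPerMicron", "MultichannelStack", function(x) x@pixelsPerMicron)
#' @rdname pixelsPerMicron
#' @export
setMethod("pixelsPerMicron", "BinaryMask", function(x) x@pixelsPerMicron)
#' @rdname pixelsPerMicron
#' @export
setMethod("pixelsPerMicron", "LabelMask", function(x) x@pixelsPerMicron)
#' @rdname pixelsPerMicron
#' @export
setMethod("pixelsPerMicron", "RadialACF", function(x) x@pixelsPerMicron)

#' @rdname sourceId
#' @export
setMethod("sourceId", "CalibratedImage", function(x) x@sourceId)
#' @rdname sourceId
#' @export
setMethod("sourceId", "RGBHistologyImage", function(x) x@sourceId)
#' @rdname sourceId
#' @export
setMethod("sourceId", "MultichannelStack", function(x) x@sourceId)

#' @rdname maskMatrix
#' @export
setMethod("maskMatrix", "BinaryMask", function(x) x@mask)

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "LabelMask", function(x) x@labels)

#' @rdname nNuclei
#' @export
setMethod("nNuclei", "LabelMask", function(x) x@nNuclei)
#' @rdname nNuclei
#' @export
setMethod("nNuclei", "LocalizationResult", function(x) x@nNuclei)

#' Accessors for radial autocorrelation profiles
#'
#' @param x a \linkS4class{RadialACF}
#' @return numeric vectors: lag bin centers (px or um), the radially averaged
#'   correlation values, and the valid-pair count per bin.
#' @name radialacf-accessors
NULL

#' @rdname radialacf-accessors
#' @export
lagsPx <- function(x) x@lagsPx
#' @rdname radialacf-accessors
#' @export
lagsUm <- function(x) x@lagsUm
#' @rdname radialacf-accessors
#' @export
acfValues <- function(x) x@values
#' @rdname radialacf-accessors
#' @export
pairCounts <- function(x) x@pairCounts

#' Accessors for correlation-length results
#'
#' @param x a \linkS4class{CorrLengthResult}
#' @return the correlation length (um or px), or the underlying profile.
#' @name corrlength-accessors
NULL

#' @rdname corrlength-accessors
#' @export
correlationLengthUm <- function(x) x@correlationLengthUm
#' @rdname corrlength-accessors
#' @export
correlationLengthPx <- function(x) x@correlationLengthPx
#' @rdname corrlength-accessors
#' @export
acfProfile <- function(x) x@profile

#' Accessors for Von Kossa quantification results
#'
#' @param x a \linkS4class{VKResult}
#' @return the requested scalar component.
#' @name vkresult-accessors
NULL

#' @rdname vkresult-accessors
#' @export
integratedDensity <- function(x) x@integratedDensity
#' @rdname vkresult-accessors
#' @export
areaFraction <- function(x) x@areaFraction
#' @rdname vkresult-accessors
#' @export
normalizedDensity <- function(x) x@normalizedDensity
#' @rdname vkresult-accessors
#' @export
thresholdUsed <- function(x) x@thresholdUsed

#' Accessors for localization results
#'
#' @param x a \linkS4class{LocalizationResult}
#' @return the requested scalar component.
#' @name localization-accessors
NULL

#' @rdname localization-accessors
#' @export
cellMean <- function(x) x@cellMean
#' @rdname localization-accessors
#' @export
ecmMean <- function(x) x@ecmMean
#' @rdname localization-accessors
#' @export
intensityRatio <- function(x) x@ratio

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CalibratedImage '%s': %d x %d px (%.1f x %.1f um) at %.3g px/um\n",
              object@sourceId, d[1], d[2],
              d[1] / object@pixelsPerMicron, d[2] / object@pixelsPerMicron,
              object@pixelsPerMicron))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "RGBHistologyImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "RGBHistologyImage '%s': %d x %d px, 3 channels (convert with rgbToGray8)\n",
    object@sourceId, d[1], d[2]))
})

setMethod("show", "MultichannelStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("MultichannelStack '%s': z=%d, channels=%d (%s), %d x %d px\n",
              object@sourceId, d[1], d[2],
              paste(object@channelRoles, collapse = ", "), d[3], d[4]))
  cat(sprintf("  %.3g px/um in-plane, z-step %.3g um\n",
              object@pixelsPerMicron, object@zStepUm))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryMask: %d x %d px, %d foreground (%.2f%%), %.3g px/um\n",
              d[1], d[2], sum(object@mask),
              100 * mean(object@mask), object@pixelsPerMicron))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d nuclei in %d x %d px\n", object@nNuclei,
              nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "RadialACF", function(object) {
  cat(sprintf("RadialACF: %d bins, lags 0..%g px (0..%.2f um)\n",
              length(object@lagsPx), max(object@lagsPx), max(object@lagsUm)))
})

setMethod("show", "CorrLengthResult", function(object) {
  cat(sprintf("CorrLengthResult: L = %.3f um (%.3f px), integrated to lag %.2f px%s%s\n",
              object@correlationLengthUm, object@correlationLengthPx,
              object@integrationUpperLagPx,
              if (object@crossedZero) "" else " [no zero crossing: lower bound]",
              if (object@lowSupport) " [low support: <10 foreground px]" else ""))
})

setMethod("show", "VKResult", function(object) {
  cat(sprintf(
    "VKResult '%s': %d foreground px, integrated density %.0f,\n  area fraction %.4f, normalized density %.4f (threshold %s)\n",
    object@sourceId, object@nForegroundPx, object@integratedDensity,
    object@areaFraction, object@normalizedDensity,
    ifelse(is.na(object@thresholdUsed), "NA", object@thresholdUsed)))
})

setMethod("show", "LocalizationResult", function(object) {
  cat(sprintf(
    "LocalizationResult '%s': cell:ECM ratio %.3f (cell %.2f / ECM %.2f)\n  %d nuclei, cellular fraction %.3f, dilation %d px\n",
    object@sourceId, object@ratio, object@cellMean, object@ecmMean,
    object@nNuclei, object@cellularFraction, object@dilationPx))
})

setMethod("show", "GroupComparisonResult", function(object) {
  cat(sprintf("GroupComparisonResult [%s]: groups %s\n", object@testName,
              paste(sprintf("%s (n=%d)", object@groups$label, object@groups$n),
                    collapse = ", ")))
  stats <- paste(sprintf("%s=%.4g (p=%.4g)",
                         names(object@statistic), object@statistic,
                         object@pValue), collapse = "; ")
  cat(" ", stats, "\n")
  if (!is.null(object@posthoc))
    cat(sprintf("  post hoc: %d adjusted comparisons\n", nrow(object@posthoc)))
})

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport: %d images, %d groups, %d comparisons\n",
              nrow(object@perImageTable),
              length(unique(object@perImageTable$group)),
              length(object@comparisons)))
})
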
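#' @import methods
NULL

## Central containers. Every image-like object carries its spatial calibration
## (pixels per micrometer) so downstream statistics can report lengths in um.

#' CalibratedImage: a single-channel intensity field with spatial calibration
#'
#' The unit every analysis stage consumes: a 2D grayscale intensity field
#' (nominally on the 8-bit 0--255 scale, stored at full precision) together
#' with the pixels-per-micrometer calibration of the acquisition.
#'
#' @slot pixels numeric matrix of nonnegative, finite intensities.
#' @slot pixelsPerMicron positive scalar calibration (px/um).
#' @slot sourceId free-text provenance label (e.g. the file name).
#' @export
setClass("CalibratedImage",
  slots = c(pixels = "matrix", pixelsPerMicron = "numeric",
            sourceId = "character"))

setValidity("CalibratedImage", function(object) {
  p <- object@pixels
  if (length(object@pixelsPerMicron) != 1L ||
      !is.finite(object@pixelsPerMicron) || object@pixelsPerMicron <= 0)
    return("pixelsPerMicron must be a single positive finite number")
  if (nrow(p) < 1L || ncol(p) < 1L)
    return("image must have both dimensions >= 1")
  if (!all(is.finite(p)) || any(p < 0))
    return("pixel intensities must be finite and >= 0")
  TRUE
})

#' RGBHistologyImage: a 3-channel brightfield raster awaiting grayscale conversion
#'
#' Container for RGB histology scans (e.g. Von Kossa sections). Not analyzed
#' directly; pass through [rgbToGray8()] first.
#'
#' @slot pixels numeric array (height, width, 3) on the 0--255 scale.
#' @slot pixelsPerMicron positive scalar calibration (px/um).
#' @slot sourceId free-text provenance label.
#' @export
setClass("RGBHistologyImage",
  slots = c(pixels = "array", pixelsPerMicron = "numeric",
            sourceId = "character"))

setValidity("RGBHistologyImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a (height, width, 3) array")
  if (length(object@pixelsPerMicron) != 1L ||
      !is.finite(object@pixelsPerMicron) || object@pixelsPerMicron <= 0)
    return("pixelsPerMicron must be a single positive finite number")
  TRUE
})

#' MultichannelStack: a calibrated multichannel z-stack
#'
#' Fluorescence z-stacks ordered (z, channel, y, x), with channel roles naming
#' which channel holds the nuclear counterstain (DAPI) and which the signal of
#' interest. Exactly one channel must carry each of the roles "nuclei" and
#' "signal"; remaining channels are "other".
#'
#' @slot voxels numeric 4-d array ordered (z, channel, y, x).
#' @slot channelRoles character vector, one role per channel, drawn from
#'   \code{c("nuclei", "signal", "other")}.
#' @slot pixelsPerMicron positive scalar in-plane calibration (px/um).
#' @slot zStepUm positive scalar axial step between slices (um).
#' @slot sourceId free-text provenance label.
#' @export
setClass("MultichannelStack",
  slots = c(voxels = "array", channelRoles = "character",
            pixelsPerMicron = "numeric", zStepUm = "numeric",
            sourceId = "character"))

setValidity("MultichannelStack", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 4L)
    return("voxels must be a 4-d array ordered (z, channel, y, x)")
  if (d[1] < 1L) return("stack must contain at least one z-slice")
  if (length(object@channelRoles) != d[2])
    return("channelRoles must name every channel")
  if (!all(object@channelRoles %in% c("nuclei", "signal", "other")))
    return("channel roles must be 'nuclei', 'signal' or 'other'")
  if (sum(object@channelRoles == "nuclei") != 1L)
    return("exactly one channel must have role 'nuclei'")
  if (sum(object@channelRoles == "signal") != 1L)
    return("exactly one channel must have role 'signal'")
  if (length(object@zStepUm) != 1L || !is.finite(object@zStepUm) ||
      object@zStepUm <= 0)
    return("zStepUm must be a single positive finite number")
  if (length(object@pixelsPerMicron) != 1L ||
      !is.finite(object@pixelsPerMicron) || object@pixelsPerMicron <= 0)
    return("pixelsPerMicron must be a single positive finite number")
  TRUE
})

#' BinaryMask: a calibrated foreground/background field
#'
#' Marks stain-positive (Von Kossa) or cellular pixels: values strictly in
#' \{0, 1\}, same shape as the image it was derived from.
#'
#' @slot mask numeric matrix with values in \{0, 1\}.
#' @slot pixelsPerMicron positive scalar calibration (px/um).
#' @export
setClass("BinaryMask",
  slots = c(mask = "matrix", pixelsPerMicron = "numeric"))

setValidity("BinaryMask", function(object) {
  if (!all(object@mask %in% c(0, 1)))
    return("mask values must be strictly in {0, 1}")
  if (length(object@pixelsPerMicron) != 1L ||
      !is.finite(object@pixelsPerMicron) || object@pixelsPerMicron <= 0)
    return("pixelsPerMicron must be a single positive finite number")
  TRUE
})

#' LabelMask: labelled nuclei
#'
#' Connected-component labelling of segmented nuclei: 0 marks background and
#' labels 1..n mark the n nuclei, numbered in row-major centroid order.
#'
#' @slot labels integer matrix of nonnegative labels.
#' @slot nNuclei integer count of nuclei.
#' @slot pixelsPerMicron positive scalar calibration (px/um).
#' @export
setClass("LabelMask",
  slots = c(labels = "matrix", nNuclei = "integer",
            pixelsPerMicron = "numeric"))

setValidity("LabelMask", function(object) {
  u <- sort(unique(as.vector(object@labels)))
  u <- u[u != 0]
  n <- object@nNuclei
  if (length(u) != n || (n > 0 && !identical(as.integer(u), seq_len(n))))
    return("labels must be consecutive 1..nNuclei")
  if (length(object@pixelsPerMicron) != 1L ||
      !is.finite(object@pixelsPerMicron) || object@pixelsPerMicron <= 0)
    return("pixelsPerMicron must be a single positive finite number")
  TRUE
})

#' LagCorrelationField: 2D lag-indexed normalized autocorrelation
#'
#' The variance-normalized autocorrelation g(dy, dx) of a binary mask on the
#' centered lag grid with max-norm radius \code{maxLagPx}, together with the
#' number of valid (non-wrapped) pixel pairs behind each lag.
#'
#' @slot g numeric matrix (2K+1 x 2K+1), lags -K..K on each axis; g(0,0) = 1.
#' @slot pairCounts numeric matrix of valid-pair counts, same shape.
#' @slot maxLagPx integer K.
#' @slot pixelsPerMicron positive scalar calibration (px/um).
#' @export
setClass("LagCorrelationField",
  slots = c(g = "matrix", pairCounts = "matrix", maxLagPx = "integer",
            pixelsPerMicron = "numeric"))

setValidity("LagCorrelationField", function(object) {
  K <- object@maxLagPx
  if (!identical(dim(object@g), as.integer(c(2 * K + 1, 2 * K + 1))))
    return("g must be (2K+1) x (2K+1)")
  if (!identical(dim(object@pairCounts), dim(object@g)))
    return("pairCounts must match g in shape")
  if (abs(object@g[K + 1, K + 1] - 1) > 1e-9)
    return("zero-lag correlation must be 1")
  TRUE
})

#' RadialACF: radially averaged autocorrelation profile
#'
#' The 2D lag field averaged into 1-px-wide annuli by Euclidean lag length:
#' bin b collects lags with length in [b - 0.5, b + 0.5) (bin 0 is the zero
#' lag alone), each value a pair-count-weighted mean of g.
#'
#' @slot lagsPx numeric, strictly increasing bin centers starting at 0.
#' @slot lagsUm the same lags in micrometers.
#' @slot values numeric correlation values; values[1] (zero lag) equals 1.
#' @slot pairCounts numeric total valid-pair count per bin.
#' @slot pixelsPerMicron positive scalar calibration (px/um).
#' @export
setClass("RadialACF",
  slots = c(lagsPx = "numeric", lagsUm = "numeric", values = "numeric",
            pairCounts = "numeric", pixelsPerMicron = "numeric"))

setValidity("RadialACF", function(object) {
  n <- length(object@lagsPx)
  if (length(object@values) != n || length(object@pairCounts) != n ||
      length(object@lagsUm) != n)
    return("lagsPx, lagsUm, values and pairCounts must have equal length")
  if (n < 1L || object@lagsPx[1] != 0 ||
      (n > 1L && any(diff(object@lagsPx) <= 0)))
    return("lags must increase strictly from 0")
  if (abs(object@values[1] - 1) > 1e-9)
    return("zero-lag value must be 1")
  if (any(object@values > 1 + 1e-9))
    return("correlation values cannot exceed 1")
  if (any(object@pairCounts <= 0))
    return("pair counts must be positive")
  TRUE
})

#' CorrLengthResult: the correlation-length summary of a mask
#'
#' Correlation length L is the trapezoidal integral of the radial
#' autocorrelation g(r) from r = 0 to its first non-positive crossing
#' (linearly interpolated); it summarizes mineral feature size, in px and um.
#'
#' @slot correlationLengthUm,correlationLengthPx nonnegative scalars.
#' @slot integrationUpperLagPx upper integration bound actually used.
#' @slot crossedZero TRUE if g reached zero within the profile; FALSE means
#'   the integral ran to the maximum lag and L is a lower bound.
#' @slot lowSupport TRUE when the mask had fewer than 10 foreground pixels.
#' @slot profile the [RadialACF-class] the length was integrated from.
#' @export
setClass("CorrLengthResult",
  slots = c(correlationLengthUm = "numeric", correlationLengthPx = "numeric",
            integrationUpperLagPx = "numeric", crossedZero = "logical",
            lowSupport = "logical", profile = "RadialACF"))

setValidity("CorrLengthResult", function(object) {
  if (object@correlationLengthPx < 0) return("correlation length must be >= 0")
  if (object@integrationUpperLagPx > max(object@profile@lagsPx) + 1e-9)
    return("integration bound cannot exceed the profile's maximum lag")
  expected <- object@correlationLengthPx / object@profile@pixelsPerMicron
  if (abs(object@correlationLengthUm - expected) > 1e-9 * (1 + expected))
    return("correlationLengthUm must equal correlationLengthPx / calibration")
  TRUE
})

#' VKResult: Von Kossa staining quantification
#'
#' Bookkeeping of a thresholded Von Kossa image: integrated density is the sum
#' of binary-image intensities (255 per foreground pixel), area fraction the
#' foreground share of the ROI, and normalized density the integrated density
#' divided by the ROI pixel count.
#'
#' @slot integratedDensity nonnegative scalar, 255 x nForegroundPx.
#' @slot areaFraction scalar in [0, 1].
#' @slot normalizedDensity integratedDensity / roiPxCount.
#' @slot thresholdUsed integer threshold on the 8-bit scale (NA if unknown).
#' @slot nForegroundPx nonnegative integer.
#' @slot roiPxCount positive integer normalizer.
#' @slot sourceId free-text provenance label.
#' @export
setClass("VKResult",
  slots = c(integratedDensity = "numeric", areaFraction = "numeric",
            normalizedDensity = "numeric", thresholdUsed = "integer",
            nForegroundPx = "integer", roiPxCount = "integer",
            sourceId = "character"))

setValidity("VKResult", function(object) {
  if (object@integratedDensity != 255 * object@nForegroundPx)
    return("integratedDensity must equal 255 * nForegroundPx")
  if (object@areaFraction < 0 || object@areaFraction > 1)
    return("areaFraction must lie in [0, 1]")
  if (abs(object@areaFraction -
          object@nForegroundPx / object@roiPxCount) > 1e-12)
    return("areaFraction must equal nForegroundPx / roiPxCount")
  TRUE
})

#' LocalizationResult: the cell:ECM intensity-ratio measurement
#'
#' Mean signal intensity over the "cellular" pixel set (DAPI-segmented nuclei
#' dilated by a disk) divided by the mean over all remaining "ECM" pixels; the
#' two sets partition the image.
#'
#' @slot cellMean,ecmMean nonnegative scalars.
#' @slot ratio cellMean / ecmMean (Inf sentinel when ecmMean is 0).
#' @slot nNuclei integer nucleus count behind the cellular set.
#' @slot cellularFraction share of image pixels classified cellular.
#' @slot dilationPx integer dilation radius used (px).
#' @slot sourceId free-text provenance label.
#' @export
setClass("LocalizationResult",
  slots = c(cellMean = "numeric", ecmMean = "numeric", ratio = "numeric",
            nNuclei = "integer", cellularFraction = "numeric",
            dilationPx = "integer", sourceId = "character"))

#' PunctaFieldSpec: parameters of the synthetic Von Kossa puncta generator
#'
#' A Boolean (germ--grain) disk model: germ centers arrive as a Poisson
#' process with intensity \code{intensityDensityPerUm2} per um^2, disk radii
#' are lognormal with the given mean and sd (of the radius itself, in um),
#' disks render dark on a light background, and Gaussian noise is added.
#'
#' @slot heightPx,widthPx positive integer image dimensions.
#' @slot intensityDensityPerUm2 nonnegative germ intensity (per um^2).
#' @slot radiusMeanUm,radiusSdUm mean and sd of disk radius (um).
#' @slot backgroundGray,foregroundGray integer gray levels, foreground darker.
#' @slot noiseSd Gaussian noise sd (gray levels).
#' @slot pixelsPerMicron positive scalar calibration (px/um).
#' @slot seed integer RNG seed; identical seeds give bit-identical fields.
#' @export
setClass("PunctaFieldSpec",
  slots = c(heightPx = "integer", widthPx = "integer",
            intensityDensityPerUm2 = "numeric", radiusMeanUm = "numeric",
            radiusSdUm = "numeric", backgroundGray = "integer",
            foregroundGray = "integer", noiseSd = "numeric",
            pixelsPerMicron = "numeric", seed = "integer"))

setValidity("PunctaFieldSpec", function(object) {
  if (object@heightPx < 1L || object@widthPx < 1L)
    return("image dimensions must be positive")
  if (object@intensityDensityPerUm2 < 0)
    return("germ intensity must be >= 0")
  if (object@radiusMeanUm <= 0 || object@radiusSdUm < 0)
    return("radius mean must be > 0 and sd >= 0")
  if (object@foregroundGray >= object@backgroundGray)
    return("foregroundGray must be darker (smaller) than backgroundGray")
  if (object@backgroundGray > 255L || object@foregroundGray < 0L)
    return("gray levels must lie in 0..255")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@pixelsPerMicron <= 0) return("calibration must be positive")
  TRUE
})

#' IFSceneSpec: parameters of the synthetic immunofluorescence scene generator
#'
#' Emulates a two-channel z-stack: elliptical nuclei (DAPI channel, blurred),
#' and a signal channel with a diffuse ECM level everywhere, an optional
#' additive perinuclear halo within \code{haloWidthUm} of each nucleus
#' boundary, and an independent signal level inside nuclei.
#'
#' @slot heightPx,widthPx,nZ positive integer scene dimensions.
#' @slot nNuclei nonnegative integer, placed without overlap by rejection.
#' @slot nucleusAxesUm semi-axes of the nuclear ellipse (um).
#' @slot haloWidthUm width of the perinuclear halo annulus (um).
#' @slot ecmLevel,haloLevel,nucleusDapiLevel,nucleusSignalLevel nonnegative
#'   gray levels; haloLevel adds to ecmLevel on the annulus.
#' @slot noiseSd per-slice Gaussian noise sd (gray levels).
#' @slot pixelsPerMicron positive in-plane calibration (px/um).
#' @slot zStepUm positive axial step (um).
#' @slot seed integer RNG seed.
#' @export
setClass("IFSceneSpec",
  slots = c(heightPx = "integer", widthPx = "integer", nZ = "integer",
            nNuclei = "integer", nucleusAxesUm = "numeric",
            haloWidthUm = "numeric", ecmLevel = "numeric",
            haloLevel = "numeric", nucleusDapiLevel = "numeric",
            nucleusSignalLevel = "numeric", noiseSd = "numeric",
            pixelsPerMicron = "numeric", zStepUm = "numeric",
            seed = "integer"))

setValidity("IFSceneSpec", function(object) {
  if (object@heightPx < 1L || object@widthPx < 1L || object@nZ < 1L)
    return("scene dimensions must be positive")
  if (object@nNuclei < 0L) return("nNuclei must be >= 0")
  if (length(object@nucleusAxesUm) != 2L || any(object@nucleusAxesUm <= 0))
    return("nucleusAxesUm must be two positive semi-axes")
  if (object@haloWidthUm <= 0) return("haloWidthUm must be > 0")
  if (any(c(object@ecmLevel, object@haloLevel, object@nucleusDapiLevel,
            object@nucleusSignalLevel) < 0))
    return("intensity levels must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@pixelsPerMicron <= 0 || object@zStepUm <= 0)
    return("calibration and z-step must be positive")
  TRUE
})

#' GroundTruth: the synthetic generator's oracle payload
#'
#' Carries the exact masks, feature radii and analytic intensity means behind
#' a generated scene, used by tests as the recovery oracle.
#'
#' @slot trueMask [BinaryMask-class] of puncta or nuclei (or NULL).
#' @slot trueRadiiUm disk radii (um; puncta fields only).
#' @slot trueLabelMask [LabelMask-class] of nuclei (IF scenes only, or NULL).
#' @slot trueCellMean,trueEcmMean,trueRatio analytic noiseless means and their
#'   ratio over the cellular/ECM partition at \code{dilationPx} (IF only).
#' @slot dilationPx integer dilation the analytic means refer to.
#' @export
setClass("GroundTruth",
  slots = c(trueMask = "ANY", trueRadiiUm = "numeric", trueLabelMask = "ANY",
            trueCellMean = "numeric", trueEcmMean = "numeric",
            trueRatio = "numeric", dilationPx = "integer"))

#' GroupComparisonResult: one group-comparison test
#'
#' @slot testName e.g. "welch_t", "one_way_anova", "two_way_anova".
#' @slot groups data.frame with columns label and n.
#' @slot statistic named numeric (t, or F per term for ANOVA).
#' @slot pValue named numeric in [0, 1], aligned with statistic.
#' @slot posthoc data.frame of adjusted pairwise comparisons (ANOVA variants
#'   only) or NULL.
#' @slot alpha nominal significance level carried for reporting.
#' @export
setClass("GroupComparisonResult",
  slots = c(testName = "character", groups = "data.frame",
            statistic = "numeric", pValue = "numeric", posthoc = "ANY",
            alpha = "numeric"))

setValidity("GroupComparisonResult", function(object) {
  p <- object@pValue
  if (any(!is.na(p) & (p < 0 | p > 1)))
    return("p-values must lie in [0, 1]")
  if (!is.null(object@posthoc) && object@testName == "welch_t")
    return("post hoc comparisons only apply to ANOVA variants")
  TRUE
})

#' StudyReport: the orchestrated end-to-end study output
#'
#' @slot perImageTable one row per input image with all stage outputs.
#' @slot groupSummaries mean, sd and n per group and measure.
#' @slot comparisons list of [GroupComparisonResult-class].
#' @slot configEcho the fully resolved configuration (including seeds and the
#'   threshold actually applied), sufficient to rerun bit-identically.
#' @export
setClass("StudyReport",
  slots = c(perImageTable = "data.frame", groupSummaries = "data.frame",
            comparisons = "list", configEcho = "list"))
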
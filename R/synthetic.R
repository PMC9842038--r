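#' Construct a PunctaFieldSpec
#'
#' @param heightPx,widthPx image dimensions in px.
#' @param intensityDensityPerUm2 Boolean-model germ intensity (per um^2).
#' @param radiusMeanUm,radiusSdUm mean and sd of the lognormal disk radius
#'   (of the radius itself, in um — not of log-radius).
#' @param backgroundGray,foregroundGray light background and dark stain gray
#'   levels (0--255, foreground < background).
#' @param noiseSd Gaussian noise sd in gray levels.
#' @param pixelsPerMicron calibration (px/um).
#' @param seed integer RNG seed.
#' @return a \linkS4class{PunctaFieldSpec}
#' @export
punctaFieldSpec <- function(heightPx = 256L, widthPx = 256L,
                            intensityDensityPerUm2 = 0.01,
                            radiusMeanUm = 1.5, radiusSdUm = 0.5,
                            backgroundGray = 220L, foregroundGray = 30L,
                            noiseSd = 5, pixelsPerMicron = 2.73,
                            seed = 1L) {
  new("PunctaFieldSpec", heightPx = as.integer(heightPx),
      widthPx = as.integer(widthPx),
      intensityDensityPerUm2 = as.numeric(intensityDensityPerUm2),
      radiusMeanUm = as.numeric(radiusMeanUm),
      radiusSdUm = as.numeric(radiusSdUm),
      backgroundGray = as.integer(backgroundGray),
      foregroundGray = as.integer(foregroundGray),
      noiseSd = as.numeric(noiseSd),
      pixelsPerMicron = as.numeric(pixelsPerMicron), seed = as.integer(seed))
}

#' Construct an IFSceneSpec
#'
#' @param heightPx,widthPx,nZ scene dimensions.
#' @param nNuclei number of non-overlapping nuclei to place.
#' @param nucleusAxesUm semi-axes of the nuclear ellipse (um).
#' @param haloWidthUm width of the perinuclear signal halo (um).
#' @param ecmLevel diffuse signal level everywhere outside nuclei.
#' @param haloLevel additive signal on the halo annulus.
#' @param nucleusDapiLevel DAPI level inside nuclei.
#' @param nucleusSignalLevel signal level inside nuclei (default: ecmLevel).
#' @param noiseSd per-slice Gaussian noise sd.
#' @param pixelsPerMicron in-plane calibration (px/um).
#' @param zStepUm axial step (um).
#' @param seed integer RNG seed.
#' @return an \linkS4class{IFSceneSpec}
#' @export
ifSceneSpec <- function(heightPx = 256L, widthPx = 256L, nZ = 4L,
                        nNuclei = 12L, nucleusAxesUm = c(5, 3.5),
                        haloWidthUm = 1.5, ecmLevel = 25, haloLevel = 205,
                        nucleusDapiLevel = 180,
                        nucleusSignalLevel = NA_real_, noiseSd = 0,
                        pixelsPerMicron = 2.73, zStepUm = 2, seed = 1L) {
  if (is.na(nucleusSignalLevel)) nucleusSignalLevel <- ecmLevel
  new("IFSceneSpec", heightPx = as.integer(heightPx),
      widthPx = as.integer(widthPx), nZ = as.integer(nZ),
      nNuclei = as.integer(nNuclei),
      nucleusAxesUm = as.numeric(nucleusAxesUm),
      haloWidthUm = as.numeric(haloWidthUm), ecmLevel = as.numeric(ecmLevel),
      haloLevel = as.numeric(haloLevel),
      nucleusDapiLevel = as.numeric(nucleusDapiLevel),
      nucleusSignalLevel = as.numeric(nucleusSignalLevel),
      noiseSd = as.numeric(noiseSd),
      pixelsPerMicron = as.numeric(pixelsPerMicron),
      zStepUm = as.numeric(zStepUm), seed = as.integer(seed))
}

#' Expected coverage fraction of a Boolean disk model
#'
#' Closed form for the stationary germ--grain model: a point is uncovered with
#' probability exp(-lambda * pi * E[R^2]), so coverage is
#' 1 - exp(-lambda * pi * (mean^2 + sd^2)).
#'
#' @param spec a \linkS4class{PunctaFieldSpec} (or lambda, mean, sd directly).
#' @param radiusMeanUm,radiusSdUm used when \code{spec} is a bare lambda.
#' @return expected coverage fraction in [0, 1].
#' @export
booleanCoverage <- function(spec, radiusMeanUm = NULL, radiusSdUm = NULL) {
  if (is(spec, "PunctaFieldSpec")) {
    lam <- spec@intensityDensityPerUm2
    er2 <- spec@radiusMeanUm^2 + spec@radiusSdUm^2
  } else {
    lam <- spec
    er2 <- radiusMeanUm^2 + radiusSdUm^2
  }
  1 - exp(-lam * pi * er2)
}

#' Germ intensity achieving a target coverage fraction
#'
#' Inverts [booleanCoverage()]: lambda = -log(1 - coverage) / (pi * E[R^2]).
#'
#' @param coverage target area fraction in [0, 1).
#' @param radiusMeanUm,radiusSdUm radius distribution (um).
#' @return germ intensity per um^2.
#' @export
lambdaForCoverage <- function(coverage, radiusMeanUm, radiusSdUm) {
  stopifnot(coverage >= 0, coverage < 1)
  -log(1 - coverage) / (pi * (radiusMeanUm^2 + radiusSdUm^2))
}

## Rasterize disks (centers/radii in px, row/col coordinates) onto a mask.
.renderDisks <- function(H, W, cy, cx, rpx) {
  mask <- matrix(0, H, W)
  for (k in seq_along(rpx)) {
    r <- rpx[k]
    y0 <- max(1L, floor(cy[k] - r)); y1 <- min(H, ceiling(cy[k] + r))
    x0 <- max(1L, floor(cx[k] - r)); x1 <- min(W, ceiling(cx[k] + r))
    if (y0 > y1 || x0 > x1) next
    ys <- y0:y1; xs <- x0:x1
    sub <- outer((ys - cy[k])^2, (xs - cx[k])^2, "+") <= r^2
    mask[ys, xs] <- pmax(mask[ys, xs], sub + 0)
  }
  mask
}

#' Generate a synthetic Von Kossa puncta field
#'
#' Boolean disk model emulating dark mineral puncta on a light tissue
#' background: disk count is Poisson in the germ intensity, centers are
#' uniform (sampled in a border-padded window so coverage is stationary on
#' the image), radii are lognormal with the specified mean and sd of the
#' radius itself, disks render at \code{foregroundGray} on
#' \code{backgroundGray}, and Gaussian noise is added then clipped to 0--255.
#' Identical seeds give bit-identical output.
#'
#' @param spec a \linkS4class{PunctaFieldSpec}.
#' @return list with elements \code{image} (\linkS4class{CalibratedImage})
#'   and \code{truth} (\linkS4class{GroundTruth} carrying the noiseless mask
#'   and the radii, in um, of the disks intersecting the image).
#' @export
genPunctaField <- function(spec) {
  stopifnot(is(spec, "PunctaFieldSpec"))
  validObject(spec)
  set.seed(spec@seed)
  ppm <- spec@pixelsPerMicron
  H <- spec@heightPx; W <- spec@widthPx
  padUm <- spec@radiusMeanUm + 8 * max(spec@radiusSdUm,
                                       0.25 * spec@radiusMeanUm)
  pad <- ceiling(padUm * ppm)
  areaUm2 <- (H + 2 * pad) * (W + 2 * pad) / ppm^2
  n <- stats::rpois(1, spec@intensityDensityPerUm2 * areaUm2)
  keptRadii <- numeric(0)
  if (n > 0) {
    cy <- stats::runif(n, 0.5 - pad, H + 0.5 + pad)
    cx <- stats::runif(n, 0.5 - pad, W + 0.5 + pad)
    if (spec@radiusSdUm == 0) {
      rum <- rep(spec@radiusMeanUm, n)
    } else {
      sdlog2 <- log(1 + spec@radiusSdUm^2 / spec@radiusMeanUm^2)
      rum <- stats::rlnorm(n, meanlog = log(spec@radiusMeanUm) - sdlog2 / 2,
                           sdlog = sqrt(sdlog2))
    }
    rpx <- rum * ppm
    hit <- cy + rpx >= 0.5 & cy - rpx <= H + 0.5 &
      cx + rpx >= 0.5 & cx - rpx <= W + 0.5
    mask <- .renderDisks(H, W, cy[hit], cx[hit], rpx[hit])
    keptRadii <- rum[hit]
  } else {
    mask <- matrix(0, H, W)
  }
  img <- matrix(spec@backgroundGray, H, W)
  img[mask == 1] <- spec@foregroundGray
  if (spec@noiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, spec@noiseSd)
  img[] <- pmin(255, pmax(0, img))
  truth <- new("GroundTruth", trueMask = BinaryMask(mask, ppm),
               trueRadiiUm = keptRadii, trueLabelMask = NULL,
               trueCellMean = numeric(0), trueEcmMean = numeric(0),
               trueRatio = numeric(0), dilationPx = NA_integer_)
  list(image = CalibratedImage(img, ppm,
                               sprintf("puncta-seed%d", spec@seed)),
       truth = truth)
}

#' Generate a synthetic immunofluorescence scene
#'
#' Builds a two-channel z-stack: elliptical nuclei (random orientation,
#' placed without overlap by rejection sampling) rendered into a DAPI channel
#' and blurred (Gaussian, sd 1 px); a signal channel with the diffuse ECM
#' level everywhere, \code{haloLevel} added on the annulus within
#' \code{haloWidthUm} of each nucleus boundary, and \code{nucleusSignalLevel}
#' inside nuclei. Both channels are replicated across z with independent
#' per-slice noise. The ground truth carries the exact label mask and the
#' analytic cell/ECM means of the noiseless signal at the nominal dilation
#' (5 px).
#'
#' @param spec an \linkS4class{IFSceneSpec}.
#' @param dilationPx nominal dilation the analytic ground-truth means refer
#'   to (default 5 px).
#' @return list with elements \code{stack}
#'   (\linkS4class{MultichannelStack}, channels ordered nuclei then signal)
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @export
genIFScene <- function(spec, dilationPx = 5L) {
  stopifnot(is(spec, "IFSceneSpec"))
  validObject(spec)
  set.seed(spec@seed)
  ppm <- spec@pixelsPerMicron
  H <- spec@heightPx; W <- spec@widthPx
  aPx <- spec@nucleusAxesUm[1] * ppm
  bPx <- spec@nucleusAxesUm[2] * ppm
  margin <- ceiling(aPx) + 1
  lab <- matrix(0L, H, W)
  occupied <- matrix(0, H, W)
  placed <- 0L
  if (spec@nNuclei > 0) {
    if (H - 2 * margin < 1 || W - 2 * margin < 1)
      stop("scene too small for the requested nucleus size")
    for (k in seq_len(spec@nNuclei)) {
      ok <- FALSE
      for (att in seq_len(1000L)) {
        cy <- stats::runif(1, margin, H - margin)
        cx <- stats::runif(1, margin, W - margin)
        th <- stats::runif(1, 0, pi)
        ys <- max(1, floor(cy - aPx - 1)):min(H, ceiling(cy + aPx + 1))
        xs <- max(1, floor(cx - aPx - 1)):min(W, ceiling(cx + aPx + 1))
        dy <- outer(ys - cy, rep(1, length(xs)))
        dx <- outer(rep(1, length(ys)), xs - cx)
        u <- dy * cos(th) + dx * sin(th)
        v <- -dy * sin(th) + dx * cos(th)
        ell <- (u / aPx)^2 + (v / bPx)^2 <= 1
        if (!any(ell)) next
        cand <- matrix(0, H, W)
        cand[ys, xs] <- ell + 0
        grown <- .dilateDisk(cand, 2L)
        if (sum(grown * occupied) == 0) {
          lab[cand == 1] <- k
          occupied <- pmax(occupied, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place nucleus ", k,
             " in 1000 attempts: reduce nNuclei or the nucleus size")
      placed <- placed + 1L
    }
  }
  lab <- .orderLabelsRowMajor(lab)
  storage.mode(lab) <- "integer"
  nuc <- (lab > 0) + 0
  haloPx <- max(1L, as.integer(round(spec@haloWidthUm * ppm)))
  halo <- .dilateDisk(nuc, haloPx) - nuc
  dapi0 <- matrix(0, H, W)
  dapi0[nuc == 1] <- spec@nucleusDapiLevel
  if (sum(nuc) > 0)
    dapi0 <- as.matrix(EBImage::gblur(dapi0, sigma = 1))
  signal0 <- matrix(spec@ecmLevel, H, W)
  signal0[halo == 1] <- spec@ecmLevel + spec@haloLevel
  signal0[nuc == 1] <- spec@nucleusSignalLevel
  vox <- array(0, dim = c(spec@nZ, 2L, H, W))
  for (z in seq_len(spec@nZ)) {
    d <- dapi0; s <- signal0
    if (spec@noiseSd > 0) {
      d <- d + stats::rnorm(length(d), 0, spec@noiseSd)
      s <- s + stats::rnorm(length(s), 0, spec@noiseSd)
    }
    vox[z, 1, , ] <- pmin(255, pmax(0, d))
    vox[z, 2, , ] <- pmin(255, pmax(0, s))
  }
  dilationPx <- as.integer(dilationPx)
  labelMask <- new("LabelMask", labels = lab, nNuclei = max(lab),
                   pixelsPerMicron = ppm)
  if (placed > 0L) {
    cellular <- .dilateDisk(nuc, dilationPx)
    tc <- mean(signal0[cellular == 1])
    te <- mean(signal0[cellular == 0])
    tr <- tc / te
  } else {
    tc <- numeric(0); te <- numeric(0); tr <- numeric(0)
  }
  truth <- new("GroundTruth", trueMask = BinaryMask(nuc, ppm),
               trueRadiiUm = numeric(0), trueLabelMask = labelMask,
               trueCellMean = tc, trueEcmMean = te, trueRatio = tr,
               dilationPx = dilationPx)
  stack <- MultichannelStack(vox, c("nuclei", "signal"), ppm, spec@zStepUm,
                             sprintf("ifscene-seed%d", spec@seed))
  list(stack = stack, truth = truth)
}

#' Named synthetic presets emulating the study conditions
#'
#' Puncta presets share one target area fraction (8\%) so that only the
#' feature-size distribution differs between them: "female_CM" uses small
#' micropunctae (radius 1.5 +/- 0.5 um), "male_CM" large nodules
#' (6 +/- 2 um), and "OM_control" has germ intensity 0 (no staining). IF
#' presets: "perinuclear_OPN" concentrates signal in a bright halo around
#' nuclei (cell:ECM ratio ~4); "diffuse_OPN" spreads signal through the ECM
#' with none inside nuclei (ratio ~0.5).
#'
#' @param name one of "female_CM", "male_CM", "OM_control",
#'   "perinuclear_OPN", "diffuse_OPN".
#' @param seed integer RNG seed for the returned spec.
#' @param ... overrides forwarded to [punctaFieldSpec()] or [ifSceneSpec()].
#' @return a \linkS4class{PunctaFieldSpec} or \linkS4class{IFSceneSpec}
#' @export
presetSpec <- function(name, seed = 1L, ...) {
  af <- 0.08   # shared nominal area fraction of the puncta presets
  switch(name,
    female_CM = punctaFieldSpec(
      intensityDensityPerUm2 = lambdaForCoverage(af, 1.5, 0.5),
      radiusMeanUm = 1.5, radiusSdUm = 0.5, seed = seed, ...),
    male_CM = punctaFieldSpec(
      intensityDensityPerUm2 = lambdaForCoverage(af, 6, 2),
      radiusMeanUm = 6, radiusSdUm = 2, seed = seed, ...),
    OM_control = punctaFieldSpec(
      intensityDensityPerUm2 = 0, radiusMeanUm = 1.5, radiusSdUm = 0.5,
      seed = seed, ...),
    perinuclear_OPN = ifSceneSpec(
      ecmLevel = 25, haloLevel = 205, nucleusSignalLevel = 25,
      seed = seed, ...),
    diffuse_OPN = ifSceneSpec(
      ecmLevel = 120, haloLevel = 0, nucleusSignalLevel = 0,
      seed = seed, ...),
    stop("unknown preset: ", name)
  )
}
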
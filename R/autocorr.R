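## Radially averaged autocorrelation and the correlation-length statistic.
##
## A binary mask is mapped to a +/-1 field s = 2*mask - 1, so a pixel pair of
## equal value contributes +1 and an opposite pair -1. For each lag vector
## D = (dy, dx) with max-norm <= K,
##
##     g(D) = ( <s(x) s(x+D)>_valid - sbar^2 ) / var(s)
##
## where the average runs over valid (non-wrapped) pixel pairs only, sbar is
## the mean of s and var(s) = 1 - sbar^2 its population variance (s^2 = 1).
## The mean subtraction and variance normalization pin g(0) = 1 and make g
## decay to ~0 at large lags, so its radial integral is a length: without
## them the raw +/-1 pair average has a nonzero large-lag baseline of
## (2p - 1)^2 at coverage p. Boundaries are handled aperiodically (zero
## padding) with a per-lag valid-pair count correction: tissue sections are
## not periodic.

.checkMaskVariance <- function(m) {
  if (all(m == m[1]))
    stop("undefined autocorrelation: zero variance")
}

.resolveMaxLag <- function(m, maxLagPx) {
  if (is.null(maxLagPx)) maxLagPx <- floor(min(dim(m)) / 4)
  maxLagPx <- as.integer(maxLagPx)
  if (maxLagPx < 1L) stop("maxLagPx must be a positive integer")
  if (maxLagPx >= min(dim(m)))
    stop("maxLagPx must be smaller than the smallest image dimension")
  maxLagPx
}

#' 2D normalized autocorrelation of a binary mask (spectral)
#'
#' Computes the variance-normalized autocorrelation g(dy, dx) of a binary
#' mask for all lag vectors with max-norm at most \code{maxLagPx}, via
#' zero-padded FFT correlation with per-lag valid-pair normalization. See
#' [acf2dBruteforce()] for the reference pair-enumeration semantics this
#' implementation must (and is tested to) reproduce.
#'
#' @param mask a \linkS4class{BinaryMask} (or bare 0/1 matrix; then the
#'   calibration defaults to 1 px/um). Must contain both values.
#' @param maxLagPx positive integer lag radius; default
#'   \code{floor(min(dim)/4)}. Must be smaller than the smallest image
#'   dimension.
#' @param normalize subtract the mean and divide by the variance (default).
#'   \code{FALSE} exports the raw +/-1 pair average, whose large-lag baseline
#'   is (2p - 1)^2 at coverage p, for comparison with conventions that skip
#'   mean subtraction.
#' @return a \linkS4class{LagCorrelationField}
#' @export
acf2d <- function(mask, maxLagPx = NULL, normalize = TRUE) {
  ppm <- if (is(mask, "BinaryMask")) mask@pixelsPerMicron else 1
  m <- .asMaskMatrix(mask)
  .checkMaskVariance(m)
  K <- .resolveMaxLag(m, maxLagPx)
  s <- 2 * m - 1
  H <- nrow(s); W <- ncol(s)
  P <- stats::nextn(H + K, c(2, 3, 5))
  Q <- stats::nextn(W + K, c(2, 3, 5))
  sp <- matrix(0, P, Q); sp[1:H, 1:W] <- s
  op <- matrix(0, P, Q); op[1:H, 1:W] <- 1
  Fs <- stats::fft(sp)
  Fo <- stats::fft(op)
  S <- Re(stats::fft(Fs * Conj(Fs), inverse = TRUE)) / (P * Q)
  N <- Re(stats::fft(Fo * Conj(Fo), inverse = TRUE)) / (P * Q)
  iy <- c((P - K + 1):P, 1:(K + 1))   # lags -K..-1, 0..K
  ix <- c((Q - K + 1):Q, 1:(K + 1))
  Ng <- round(N[iy, ix])
  sbar <- mean(s)
  v <- 1 - sbar^2
  g <- if (normalize) (S[iy, ix] / Ng - sbar^2) / v else S[iy, ix] / Ng
  g[K + 1, K + 1] <- 1   # zero lag is exact by construction (s^2 = 1)
  new("LagCorrelationField", g = g, pairCounts = Ng, maxLagPx = K,
      pixelsPerMicron = ppm)
}

#' 2D normalized autocorrelation by direct pair enumeration (oracle)
#'
#' Reference implementation of the identical definition as [acf2d()], by a
#' direct loop over lag vectors with explicit overlap sums — no spectral
#' shortcut. Quadratic cost; intended for small masks and as the independent
#' oracle in tests.
#'
#' @inheritParams acf2d
#' @return a \linkS4class{LagCorrelationField}
#' @export
acf2dBruteforce <- function(mask, maxLagPx = NULL, normalize = TRUE) {
  ppm <- if (is(mask, "BinaryMask")) mask@pixelsPerMicron else 1
  m <- .asMaskMatrix(mask)
  .checkMaskVariance(m)
  K <- .resolveMaxLag(m, maxLagPx)
  s <- 2 * m - 1
  H <- nrow(s); W <- ncol(s)
  sbar <- mean(s)
  v <- 1 - sbar^2
  g <- matrix(NA_real_, 2 * K + 1, 2 * K + 1)
  N <- matrix(NA_real_, 2 * K + 1, 2 * K + 1)
  for (dy in -K:K) {
    y1 <- max(1, 1 - dy); y2 <- min(H, H - dy)
    for (dx in -K:K) {
      x1 <- max(1, 1 - dx); x2 <- min(W, W - dx)
      A <- s[y1:y2, x1:x2, drop = FALSE]
      B <- s[(y1 + dy):(y2 + dy), (x1 + dx):(x2 + dx), drop = FALSE]
      n <- length(A)
      raw <- sum(A * B) / n
      g[dy + K + 1, dx + K + 1] <- if (normalize) (raw - sbar^2) / v else raw
      N[dy + K + 1, dx + K + 1] <- n
    }
  }
  new("LagCorrelationField", g = g, pairCounts = N, maxLagPx = K,
      pixelsPerMicron = ppm)
}

#' Radially average a 2D lag correlation field
#'
#' Bins lag vectors by Euclidean length into 1-px-wide annuli centered at
#' integers (bin b collects lengths in [b - 0.5, b + 0.5); bin 0 is the zero
#' lag alone) and averages g within each annulus weighted by valid-pair
#' counts. The lag (3, 4) therefore lands in bin 5.
#'
#' @param field a \linkS4class{LagCorrelationField} from [acf2d()] or
#'   [acf2dBruteforce()].
#' @return a \linkS4class{RadialACF}
#' @export
radialAverage <- function(field) {
  stopifnot(is(field, "LagCorrelationField"))
  K <- field@maxLagPx
  d <- (-K):K
  r <- sqrt(outer(d^2, d^2, "+"))
  b <- floor(r + 0.5)
  w <- field@pairCounts
  gw <- rowsum(as.vector(field@g * w), as.vector(b))
  ww <- rowsum(as.vector(w), as.vector(b))
  lags <- as.numeric(rownames(gw))
  ord <- order(lags)
  new("RadialACF",
      lagsPx = lags[ord],
      lagsUm = lags[ord] / field@pixelsPerMicron,
      values = (gw / ww)[ord],
      pairCounts = ww[ord],
      pixelsPerMicron = field@pixelsPerMicron)
}

#' Correlation length: the integral of the radial autocorrelation
#'
#' Integrates g(r) by the trapezoid rule from r = 0 to its first non-positive
#' value, linearly interpolating the zero crossing; this operationalizes the
#' maximum radial distance at which features remain segregated from their
#' surroundings, i.e. a feature-size length scale. If g never reaches zero the
#' profile is integrated to its maximum lag and the result is flagged
#' (\code{crossedZero = FALSE}): it is then a lower bound that depends on the
#' chosen maximum lag.
#'
#' @param profile a \linkS4class{RadialACF}.
#' @param toCrossing integrate to the first non-positive crossing (default);
#'   \code{FALSE} always integrates to the maximum lag.
#' @param lowSupport flag carried into the result (set by
#'   [maskCorrelationLength()] for masks with fewer than 10 foreground px).
#' @return a \linkS4class{CorrLengthResult}
#' @export
correlationLength <- function(profile, toCrossing = TRUE,
                              lowSupport = FALSE) {
  stopifnot(is(profile, "RadialACF"))
  r <- profile@lagsPx
  g <- profile@values
  if (length(r) < 2L)
    stop("profile must contain at least 2 lag bins")
  cross <- if (toCrossing) which(g[-1] <= 0) else integer(0)
  if (length(cross) > 0) {
    i <- cross[1] + 1L               # first non-positive bin
    rstar <- if (g[i] == 0) r[i] else
      r[i - 1] + g[i - 1] * (r[i] - r[i - 1]) / (g[i - 1] - g[i])
    L <- 0
    if (i > 2L) {
      idx <- 1:(i - 1L)
      L <- sum(diff(r[idx]) * (g[idx][-1] + g[idx][-length(idx)]) / 2)
    }
    L <- L + g[i - 1] * (rstar - r[i - 1]) / 2   # triangle to the crossing
    crossed <- TRUE
    upper <- rstar
  } else {
    L <- sum(diff(r) * (g[-1] + g[-length(g)]) / 2)
    crossed <- FALSE
    upper <- r[length(r)]
  }
  L <- max(0, L)
  new("CorrLengthResult",
      correlationLengthUm = L / profile@pixelsPerMicron,
      correlationLengthPx = L,
      integrationUpperLagPx = upper,
      crossedZero = crossed, lowSupport = lowSupport, profile = profile)
}

#' Correlation length of a binary mask (full pipeline)
#'
#' Convenience wrapper: [acf2d()] then [radialAverage()] then
#' [correlationLength()]. Masks with fewer than 10 foreground pixels are
#' processed but flagged low-support.
#'
#' @inheritParams acf2d
#' @param toCrossing see [correlationLength()].
#' @return a \linkS4class{CorrLengthResult}
#' @export
maskCorrelationLength <- function(mask, maxLagPx = NULL, toCrossing = TRUE) {
  m <- .asMaskMatrix(mask)
  correlationLength(radialAverage(acf2d(mask, maxLagPx)),
                    toCrossing = toCrossing,
                    lowSupport = sum(m) < 10)
}

#' Export a radial autocorrelation profile as a data.frame
#'
#' One row per lag bin with the lag in px and um, the correlation value and
#' the valid-pair count — the per-image profile behind published radial
#' autocorrelation curves.
#'
#' @param profile a \linkS4class{RadialACF}.
#' @return data.frame with columns lag_px, lag_um, g, pair_count.
#' @export
acfProfileTable <- function(profile) {
  stopifnot(is(profile, "RadialACF"))
  data.frame(lag_px = profile@lagsPx, lag_um = profile@lagsUm,
             g = profile@values, pair_count = profile@pairCounts)
}
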
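test_that("brute-force autocorrelation matches hand enumeration on a 5x5 mask", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  f <- acf2dBruteforce(BinaryMask(m, 1), 2)
  K <- 2
  sbar <- (1 - 24) / 25
  v <- 1 - sbar^2
  expect_equal(f@g[K + 1, K + 1], 1)
  # lag (0,1): 20 valid pairs, 2 of them mixed (+1 x -1), 18 equal
  expect_equal(f@g[K + 1, K + 2], ((18 - 2) / 20 - sbar^2) / v)
  expect_equal(f@pairCounts[K + 1, K + 2], 20)
})

test_that("the 2x2 checkerboard anticorrelates perfectly at unit lag", {
  cb <- matrix(c(1, 0, 0, 1), 2, 2)
  f <- acf2dBruteforce(BinaryMask(cb, 1), 1)
  expect_equal(f@g[2, 3], -1)   # lag (0,1): both valid pairs opposite
  expect_equal(f@g[3, 2], -1)   # lag (1,0)
})

test_that("spectral and brute-force autocorrelation agree to 1e-8", {
  for (s in 1:6) {
    m <- randomMask(32, 40, p = 0.3, seed = s)
    g1 <- acf2d(BinaryMask(m, 1), 10)@g
    g2 <- acf2dBruteforce(BinaryMask(m, 1), 10)@g
    expect_lt(max(abs(g1 - g2)), 1e-8)
  }
})

test_that("autocorrelation is symmetric, inversion-invariant, and pins g(0)=1", {
  m <- randomMask(40, 40, p = 0.4, seed = 9)
  f <- acf2d(BinaryMask(m, 1), 12)
  K <- f@maxLagPx
  expect_equal(f@g[K + 1, K + 1], 1)
  expect_equal(f@g, f@g[(2 * K + 1):1, (2 * K + 1):1])        # g(D) = g(-D)
  inv <- acf2d(BinaryMask(1 - m, 1), 12)
  expect_equal(f@g, inv@g, tolerance = 1e-12)
})

test_that("degenerate masks are rejected", {
  expect_error(acf2d(BinaryMask(matrix(1, 8, 8), 1), 2), "zero variance")
  expect_error(acf2dBruteforce(BinaryMask(matrix(0, 8, 8), 1), 2),
               "zero variance")
  expect_error(acf2d(BinaryMask(diag(8), 1), 10), "smaller")
})

test_that("radial averaging bins by Euclidean length with pair-count weights", {
  m <- randomMask(36, 36, p = 0.3, seed = 12)
  f <- acf2d(BinaryMask(m, 2), 11)
  p <- radialAverage(f)
  oracle <- radialOracle(f)
  expect_equal(p@values, unname(oracle), tolerance = 1e-10)
  expect_equal(p@values[1], 1)
  expect_equal(p@lagsUm, p@lagsPx / 2)
  # the (3,4) lag lands in bin 5
  expect_equal(floor(sqrt(3^2 + 4^2) + 0.5), 5)
  expect_true(all(diff(p@lagsPx) > 0))

  # an exactly radial field is a fixed point at integer lags
  K <- 6
  d <- (-K):K
  r <- sqrt(outer(d^2, d^2, "+"))
  fr <- new("LagCorrelationField", g = exp(-r), pairCounts = matrix(1, 13, 13),
            maxLagPx = 6L, pixelsPerMicron = 1)
  pr <- radialAverage(fr)
  expect_equal(pr@values[pr@lagsPx == 0], 1)
  expect_equal(pr@values[pr@lagsPx == 3],
               mean(exp(-r[abs(r - 3) < 0.5])))
})

test_that("correlation length integrates to the interpolated zero crossing", {
  prof <- new("RadialACF", lagsPx = 0:5, lagsUm = 0:5,
              values = c(1, 0, 0, 0, 0, 0), pairCounts = rep(1, 6),
              pixelsPerMicron = 1)
  cl <- correlationLength(prof)
  expect_equal(correlationLengthPx(cl), 0.5)
  expect_equal(cl@integrationUpperLagPx, 1)
  expect_true(cl@crossedZero)

  # no crossing: integrate to max lag and flag
  prof2 <- new("RadialACF", lagsPx = 0:3, lagsUm = 0:3,
               values = c(1, 0.8, 0.6, 0.4), pairCounts = rep(1, 4),
               pixelsPerMicron = 1)
  cl2 <- correlationLength(prof2)
  expect_false(cl2@crossedZero)
  expect_equal(correlationLengthPx(cl2), 0.9 + 0.7 + 0.5)

  expect_error(correlationLength(
    new("RadialACF", lagsPx = 0, lagsUm = 0, values = 1, pairCounts = 1,
        pixelsPerMicron = 1)), "at least 2")

  # um conversion flows through the calibration
  prof3 <- new("RadialACF", lagsPx = 0:5, lagsUm = (0:5) / 2.73,
               values = c(1, 0, 0, 0, 0, 0), pairCounts = rep(1, 6),
               pixelsPerMicron = 2.73)
  expect_equal(correlationLengthUm(correlationLength(prof3)), 0.5 / 2.73)
})

test_that("a single disk's correlation length matches the brute-force pipeline", {
  m <- diskMask(10, 128)
  bm <- BinaryMask(m, 1)
  Lf <- correlationLength(radialAverage(acf2d(bm, 30)))
  Lb <- correlationLength(radialAverage(acf2dBruteforce(bm, 30)))
  expect_lt(abs(correlationLengthPx(Lf) - correlationLengthPx(Lb)), 1e-8)
})

test_that("correlation length is insensitive to feature translation", {
  L1 <- correlationLengthPx(maskCorrelationLength(
    BinaryMask(diskMask(8, 128, cy = 64.5, cx = 64.5), 1), 32))
  L2 <- correlationLengthPx(maskCorrelationLength(
    BinaryMask(diskMask(8, 128, cy = 40.5, cx = 85.5), 1), 32))
  expect_lt(abs(L1 - L2) / L1, 0.01)
})

test_that("larger features correlate over longer distances, linearly in radius", {
  Rs <- c(3, 6, 12, 24)
  Ls <- vapply(Rs, function(R)
    correlationLengthPx(maskCorrelationLength(
      BinaryMask(diskMask(R, 256), 2.73))), numeric(1))
  expect_true(all(diff(Ls) > 0))
  expect_gt(summary(lm(Ls ~ Rs))$r.squared, 0.98)
})

test_that("equal-coverage presets separate by feature size at every seed", {
  for (s in 1:3) {
    lf <- maskCorrelationLength(
      genPunctaField(presetSpec("female_CM", seed = s, noiseSd = 0))$truth@trueMask)
    lm_ <- maskCorrelationLength(
      genPunctaField(presetSpec("male_CM", seed = s, noiseSd = 0))$truth@trueMask)
    expect_gt(correlationLengthUm(lm_), correlationLengthUm(lf))
  }
})

test_that("low-support masks are flagged, not dropped", {
  m <- matrix(0, 64, 64); m[30:31, 30:31] <- 1
  res <- maskCorrelationLength(BinaryMask(m, 1))
  expect_true(res@lowSupport)
  expect_gt(correlationLengthPx(res), 0)
})

test_that("the raw profile keeps the (2p-1)^2 large-lag baseline", {
  m <- randomMask(64, 64, p = 0.3, seed = 31)
  raw <- radialAverage(acf2d(BinaryMask(m, 1), 16, normalize = FALSE))
  base <- (2 * mean(m) - 1)^2
  tail <- raw@values[raw@lagsPx >= 8]
  expect_lt(max(abs(tail - base)), 0.05)
})
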
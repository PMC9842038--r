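test_that("median projection matches the per-pixel sort oracle", {
  # identical slices project to the slice itself
  sl <- matrix(7, 4, 4)
  vox <- array(0, dim = c(3, 2, 4, 4))
  for (z in 1:3) { vox[z, 1, , ] <- sl; vox[z, 2, , ] <- sl * 2 }
  st <- MultichannelStack(vox, c("nuclei", "signal"), 1, 1)
  expect_equal(unname(pixels(medianProjection(st, "signal"))), unname(sl * 2))

  # even z count: mean of the two central order statistics
  vox4 <- array(0, dim = c(4, 2, 1, 1))
  vox4[, 2, 1, 1] <- c(1, 2, 3, 100)
  vox4[, 1, 1, 1] <- 0
  st4 <- MultichannelStack(vox4, c("nuclei", "signal"), 1, 1)
  expect_equal(pixels(medianProjection(st4, "signal"))[1, 1], 2.5)

  set.seed(41)
  voxr <- array(runif(4 * 2 * 16 * 16, 0, 255), dim = c(4, 2, 16, 16))
  str <- MultichannelStack(voxr, c("nuclei", "signal"), 1, 1)
  proj <- pixels(medianProjection(str, "nuclei"))
  oracle <- apply(voxr[, 1, , ], c(2, 3), function(v) mean(sort(v)[2:3]))
  expect_equal(unname(proj), unname(oracle))
})

test_that("nuclear segmentation recovers well-separated synthetic nuclei", {
  blank <- CalibratedImage(matrix(0, 32, 32), 1)
  expect_warning(lab0 <- segmentNuclei(blank), "constant")
  expect_equal(nNuclei(lab0), 0L)

  # one bright centered disk
  disk <- CalibratedImage(200 * diskMask(8, 64), 1)
  lab1 <- segmentNuclei(disk)
  expect_equal(nNuclei(lab1), 1L)
  ctr <- which(labelMatrix(lab1) == 1, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(ctr) - 32.5)), 1)

  # noiseless generated scene: counts and centroids match ground truth
  sc <- genIFScene(presetSpec("perinuclear_OPN", seed = 8, nNuclei = 5L))
  lab <- segmentNuclei(medianProjection(sc$stack, "nuclei"))
  expect_equal(nNuclei(lab), 5L)
  truthLab <- labelMatrix(sc$truth@trueLabelMask)
  for (k in 1:5) {
    got <- which(labelMatrix(lab) == k, arr.ind = TRUE)
    want <- which(truthLab == k, arr.ind = TRUE)
    expect_lt(max(abs(colMeans(got) - colMeans(want))), 2)
  }
})

test_that("minimum-area filtering removes debris objects", {
  img <- matrix(0, 64, 64)
  img[10:20, 10:20] <- 200   # 121 px object
  img[40, 40] <- 200         # 1 px debris
  lab <- segmentNuclei(CalibratedImage(img, 1), minAreaPx = 50L)
  expect_equal(nNuclei(lab), 1L)
  lab2 <- segmentNuclei(CalibratedImage(img, 1), minAreaPx = 1L)
  expect_equal(nNuclei(lab2), 2L)
})

test_that("nucleus dilation uses an exact Euclidean disk and is monotone", {
  one <- matrix(0L, 7, 7); one[4, 4] <- 1L
  lm1 <- new("LabelMask", labels = one, nNuclei = 1L, pixelsPerMicron = 1)
  d0 <- maskMatrix(dilateNuclei(lm1, 0))
  expect_equal(sum(d0), 1)
  d1 <- maskMatrix(dilateNuclei(lm1, 1))
  expect_equal(sum(d1), 5)                       # the 5-px plus shape
  expect_equal(d1[3:5, 3:5],
               matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3))
  sizes <- vapply(0:3, function(r) sum(maskMatrix(dilateNuclei(lm1, r))),
                  numeric(1))
  expect_true(all(diff(sizes) > 0))
  expect_true(all(d0[d1 == 0] == 0))             # superset property
})

test_that("cell:ECM ratio follows its construction and partitions the image", {
  cellmask <- BinaryMask(diskMask(6, 32), 1)
  u <- CalibratedImage(matrix(42, 32, 32), 1)
  expect_equal(intensityRatio(cellEcmRatio(u, cellmask)), 1)

  img <- matrix(50, 32, 32)
  img[maskMatrix(cellmask) == 1] <- 200
  r <- cellEcmRatio(CalibratedImage(img, 1), cellmask)
  expect_equal(intensityRatio(r), 4)
  expect_equal(cellMean(r), 200)
  expect_equal(ecmMean(r), 50)
  expect_equal(r@cellularFraction * 32 * 32 +
                 (1 - r@cellularFraction) * 32 * 32, 1024)

  expect_error(cellEcmRatio(u, BinaryMask(matrix(0, 32, 32), 1)),
               "degenerate partition")
  expect_error(cellEcmRatio(u, BinaryMask(matrix(1, 32, 32), 1)),
               "degenerate partition")
  dark <- CalibratedImage(ifelse(maskMatrix(cellmask) == 1, 10, 0) +
                            matrix(0, 32, 32), 1)
  expect_warning(rz <- cellEcmRatio(dark, cellmask), "Inf")
  expect_equal(intensityRatio(rz), Inf)
})

test_that("the ratio is scale-invariant and monotone in cellular intensity", {
  set.seed(43)
  img <- matrix(runif(1024, 10, 200), 32, 32)
  cellmask <- BinaryMask(diskMask(7, 32), 1)
  r1 <- intensityRatio(cellEcmRatio(CalibratedImage(img, 1), cellmask))
  for (c_ in c(0.5, 3, 17)) {
    rc <- intensityRatio(cellEcmRatio(CalibratedImage(img * c_, 1), cellmask))
    expect_equal(rc, r1, tolerance = 1e-12)
  }
  up <- img; up[maskMatrix(cellmask) == 1] <- up[maskMatrix(cellmask) == 1] + 5
  expect_gt(intensityRatio(cellEcmRatio(CalibratedImage(up, 1), cellmask)), r1)
})

test_that("mean fluorescence equals the direct summation oracle", {
  expect_equal(meanFluorescence(CalibratedImage(matrix(42, 8, 8), 1)), 42)
  half <- CalibratedImage(cbind(matrix(0, 8, 4), matrix(100, 8, 4)), 1)
  expect_equal(meanFluorescence(half), 50)
  set.seed(44)
  img <- matrix(runif(256, 0, 255), 16, 16)
  roi <- matrix(rbinom(256, 1, 0.4), 16, 16)
  expect_equal(meanFluorescence(CalibratedImage(img, 1), BinaryMask(roi, 1)),
               sum(img[roi == 1]) / sum(roi))
  expect_error(meanFluorescence(CalibratedImage(img, 1),
                                BinaryMask(matrix(0, 16, 16), 1)), "empty")
})

test_that("noiseless scenes with ground-truth masks recover the true ratio exactly", {
  for (preset in c("diffuse_OPN", "perinuclear_OPN")) {
    sc <- genIFScene(presetSpec(preset, seed = 13))
    sig <- medianProjection(sc$stack, "signal")
    cellular <- dilateNuclei(sc$truth@trueLabelMask, sc$truth@dilationPx)
    got <- intensityRatio(cellEcmRatio(sig, cellular))
    expect_equal(got, sc$truth@trueRatio, tolerance = 1e-10)
  }
  # a uniform-signal scene has ratio exactly 1
  scu <- genIFScene(ifSceneSpec(haloLevel = 0, ecmLevel = 60,
                                nucleusSignalLevel = 60, seed = 13))
  expect_equal(scu$truth@trueRatio, 1)
  sig <- medianProjection(scu$stack, "signal")
  cellular <- dilateNuclei(scu$truth@trueLabelMask, 5)
  expect_equal(intensityRatio(cellEcmRatio(sig, cellular)), 1,
               tolerance = 1e-12)
})
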
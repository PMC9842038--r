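test_that("generation is fully deterministic under the seed", {
  sp <- presetSpec("female_CM", seed = 17)
  g1 <- genPunctaField(sp)
  g2 <- genPunctaField(sp)
  expect_identical(pixels(g1$image), pixels(g2$image))
  expect_identical(maskMatrix(g1$truth@trueMask), maskMatrix(g2$truth@trueMask))
  g3 <- genPunctaField(presetSpec("female_CM", seed = 18))
  expect_false(identical(pixels(g1$image), pixels(g3$image)))

  s1 <- genIFScene(presetSpec("perinuclear_OPN", seed = 17, noiseSd = 10))
  s2 <- genIFScene(presetSpec("perinuclear_OPN", seed = 17, noiseSd = 10))
  expect_identical(s1$stack@voxels, s2$stack@voxels)
})

test_that("an empty Boolean model yields a blank field", {
  g <- genPunctaField(presetSpec("OM_control", seed = 2))
  expect_equal(sum(maskMatrix(g$truth@trueMask)), 0)
  expect_equal(length(g$truth@trueRadiiUm), 0L)
  # noise only: all pixels near background
  expect_lt(max(abs(pixels(g$image) - 220)), 30)
})

test_that("observed coverage matches the Boolean closed form within MC error", {
  sp <- presetSpec("female_CM")
  target <- booleanCoverage(sp)
  expect_equal(target, 0.08)
  af <- vapply(1:20, function(s)
    mean(maskMatrix(genPunctaField(presetSpec("female_CM",
                                              seed = s))$truth@trueMask)),
    numeric(1))
  se <- sd(af) / sqrt(length(af))
  expect_lt(abs(mean(af) - target), 3 * se)
})

test_that("coverage distributions are seed-stable across batches", {
  af <- function(seeds) vapply(seeds, function(s)
    mean(maskMatrix(genPunctaField(presetSpec("female_CM",
                                              seed = s))$truth@trueMask)),
    numeric(1))
  ks <- suppressWarnings(ks.test(af(1:15), af(101:115)))
  expect_gt(ks$p.value, 0.01)
})

test_that("presets encode the study's design contracts", {
  expect_equal(presetSpec("OM_control")@intensityDensityPerUm2, 0)
  f <- presetSpec("female_CM"); m <- presetSpec("male_CM")
  expect_gt(m@radiusMeanUm, f@radiusMeanUm)
  expect_equal(booleanCoverage(f), booleanCoverage(m))   # equal area fraction
  expect_error(presetSpec("no_such_condition"), "unknown preset")
})

test_that("generated images round-trip through the image IO layer losslessly", {
  g <- genPunctaField(presetSpec("male_CM", seed = 3, noiseSd = 0))
  f <- withr::local_tempfile(fileext = ".tif")
  writeCalibratedImage(g$image, f, 16L)
  back <- readCalibratedImage(f, pixelsPerMicron(g$image))
  expect_equal(max(abs(pixels(back) - pixels(g$image))), 0)

  sc <- genIFScene(presetSpec("diffuse_OPN", seed = 3))
  fs <- withr::local_tempfile(fileext = ".tif")
  writeMultichannelStack(sc$stack, fs)
  back2 <- readMultichannelStack(fs, c("nuclei", "signal"),
                                 pixelsPerMicron(sc$stack),
                                 sc$stack@zStepUm)
  expect_equal(max(abs(back2@voxels - round(sc$stack@voxels))), 0)
})

test_that("ground truth is self-consistent with the rendered scene", {
  sc <- genIFScene(presetSpec("perinuclear_OPN", seed = 21))  # noiseless
  sig <- matrix(sc$stack@voxels[1, 2, , ],
                dim(sc$stack@voxels)[3], dim(sc$stack@voxels)[4])
  cellular <- maskMatrix(dilateNuclei(sc$truth@trueLabelMask,
                                      sc$truth@dilationPx))
  expect_equal(mean(sig[cellular == 1]), sc$truth@trueCellMean)
  expect_equal(mean(sig[cellular == 0]), sc$truth@trueEcmMean)
  expect_equal(sc$truth@trueRatio,
               sc$truth@trueCellMean / sc$truth@trueEcmMean)
  # perinuclear concentration pushes the true ratio above 1
  expect_gt(sc$truth@trueRatio, 1)
  # diffuse ECM signal with nuclear exclusion keeps it at or below 1
  expect_lte(genIFScene(presetSpec("diffuse_OPN", seed = 21))$truth@trueRatio, 1)
})

test_that("empty scenes are valid and segment to zero nuclei", {
  sc <- genIFScene(presetSpec("perinuclear_OPN", seed = 5, nNuclei = 0L))
  expect_equal(sc$truth@trueLabelMask@nNuclei, 0L)
  sig <- matrix(sc$stack@voxels[1, 2, , ], 256, 256)
  expect_equal(max(abs(sig - 25)), 0)
  expect_warning(lab <- segmentNuclei(medianProjection(sc$stack, "nuclei")))
  expect_equal(nNuclei(lab), 0L)
})

test_that("invalid generator specifications are rejected", {
  expect_error(punctaFieldSpec(foregroundGray = 240L, backgroundGray = 220L),
               "darker")
  expect_error(punctaFieldSpec(radiusMeanUm = 0), "> 0")
  expect_error(ifSceneSpec(nNuclei = -1L), ">= 0")
  # overcrowded scenes fail with placement advice, not silently
  expect_error(genIFScene(ifSceneSpec(heightPx = 64L, widthPx = 64L,
                                      nNuclei = 40L)),
               "reduce")
})
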
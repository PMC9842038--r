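test_that("Welch t matches the hand-evaluated formula and its symmetries", {
  same <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same@statistic), 0)
  expect_equal(unname(same@pValue), 1)

  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  r <- welchT(a, b)
  o <- welchOracle(a, b)
  expect_equal(unname(r@statistic), o$t)
  expect_equal(unname(r@pValue), o$p)

  swap <- welchT(b, a)
  expect_equal(unname(swap@statistic), -unname(r@statistic))
  expect_equal(unname(swap@pValue), unname(r@pValue))
  expect_error(welchT(1, c(1, 2)), "at least 2")
  expect_null(r@posthoc)
})

test_that("one-way ANOVA handles null data and reduces to t on two groups", {
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  nullcase <- oneWayAnova(v, g, posthoc = "dunnett", control = "a")
  expect_equal(unname(nullcase@statistic), 0)
  expect_equal(unname(nullcase@pValue), 1)
  expect_true(all(nullcase@posthoc$p_adjusted == 1))

  set.seed(51)
  x <- rnorm(8); y <- rnorm(8, 1)
  an <- oneWayAnova(c(x, y), rep(c("x", "y"), each = 8))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(unname(an@statistic), unname(tt$statistic)^2)
  expect_equal(unname(an@pValue), tt$p.value)
  expect_error(oneWayAnova(c(x, y), rep(c("x", "y"), each = 8),
                           posthoc = "dunnett"), "control")
})

test_that("Dunnett adjustment is deterministic, ordered, and bounded by Tukey-style inflation", {
  set.seed(52)
  vals <- c(rnorm(6), rnorm(6, 1), rnorm(6, 2))
  grp <- rep(c("ctl", "lo", "hi"), each = 6)
  r1 <- oneWayAnova(vals, grp, posthoc = "dunnett", control = "ctl")
  r2 <- oneWayAnova(vals, grp, posthoc = "dunnett", control = "ctl")
  expect_identical(r1@posthoc, r2@posthoc)    # fixed integration seed
  expect_true(all(r1@posthoc$p_adjusted >= r1@posthoc$p_unadjusted))
  expect_true(all(r1@posthoc$p_adjusted <= 1))

  tk <- oneWayAnova(vals, grp, posthoc = "tukey")
  expect_equal(nrow(tk@posthoc), 3)           # all pairs
  expect_true(all(tk@posthoc$p_adjusted >= 0 & tk@posthoc$p_adjusted <= 1))
})

test_that("two-way ANOVA reproduces the hand-computed sum-of-squares partition", {
  # balanced 2x2 with n = 3 per cell
  set.seed(53)
  A <- rep(rep(c("F", "M"), each = 3), 2)
  B <- rep(c("OM", "CM"), each = 6)
  y <- rnorm(12, mean = 2 * (A == "M") + 3 * (B == "CM"))
  r <- twoWayAnova(y, A, B)

  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  ssA <- 6 * sum((mA - grand)^2)
  ssB <- 6 * sum((mB - grand)^2)
  ssCell <- 3 * sum((mAB - grand)^2)
  ssAB <- ssCell - ssA - ssB
  ssE <- sum((y - mAB[interaction(A, B)])^2)
  expect_equal(unname(r@statistic["factor_a"]), (ssA / 1) / (ssE / 8))
  expect_equal(unname(r@statistic["factor_b"]), (ssB / 1) / (ssE / 8))
  expect_equal(unname(r@statistic["interaction"]), (ssAB / 1) / (ssE / 8))

  # pure additive effects, no noise: interaction F pinned to 0
  ya <- 2 * (A == "M") + 3 * (B == "CM")
  ra <- twoWayAnova(ya, A, B)
  expect_equal(unname(ra@statistic["interaction"]), 0)
  expect_equal(unname(ra@pValue["interaction"]), 1)

  # consistent relabeling leaves the inference unchanged
  relab <- twoWayAnova(y, c(F = "XX", M = "XY")[A], c(OM = "o", CM = "c")[B])
  expect_equal(unname(relab@pValue), unname(r@pValue))

  expect_error(twoWayAnova(y[-1], A[-1], B[-1]), "unbalanced")
  expect_error(twoWayAnova(y[1:6], A[1:6], B[1:6]), "full factorial")
})

test_that("run_study aggregates per-image rows and the configured comparison", {
  cfg <- dimorphismConfig(seed = 1)
  cfg$comparisons <- cfg$comparisons[1]
  rep1 <- runStudy(cfg)
  pt <- rep1@perImageTable
  expect_equal(nrow(pt), 14)
  expect_equal(sum(pt$group == "female_CM"), 7)
  expect_equal(anyDuplicated(pt$source_id), 0)
  expect_true(all(!is.na(pt$correlation_length_um)))
  expect_length(rep1@comparisons, 1)
  expect_equal(rep1@comparisons[[1]]@testName, "welch_t")
  # one threshold uniformly applied across conditions
  expect_equal(length(unique(pt$threshold_used)), 1L)
  # config echo records the resolved threshold
  expect_false(is.na(rep1@configEcho$threshold_used))
})

test_that("rerunning a study under the same config is byte-identical", {
  cfg <- dimorphismConfig(seed = 4, nImages = 3L)
  r1 <- runStudy(cfg)
  r2 <- runStudy(cfg)
  expect_identical(r1@perImageTable, r2@perImageTable)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeStudyReport(r1, d1)
  writeStudyReport(r2, d2)
  for (f in c("per_image.csv", "group_summaries.csv", "comparisons.csv",
              "report.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})
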
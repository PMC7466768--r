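test_that("the default acceptance threshold is 1.96 x 0.05", {
  expect_identical(loaThreshold(), 1.96 * 0.05)
  expect_equal(loaThreshold(), 0.098)
})

test_that("Bland-Altman summaries match hand computation", {
  x <- seq(0.1, 1, by = 0.1)
  r <- blandAltman(x, x)
  expect_equal(r@meanDiff, 0)
  expect_equal(r@sdDiff, 0)
  expect_equal(c(r@loaLower, r@loaUpper), c(0, 0))
  expect_true(r@withinThreshold)

  r2 <- blandAltman(x, x - 0.02)
  expect_equal(r2@meanDiff, 0.02)
  expect_equal(r2@sdDiff, 0)
  expect_true(r2@withinThreshold)

  # diffs {-0.01, 0, 0.01, 0.04}: mean 0.01, n-1 SD 0.02160247,
  # LoA 0.01 -/+ 1.96 * SD
  y <- c(0.30, 0.40, 0.50, 0.60)
  x3 <- y + c(-0.01, 0.00, 0.01, 0.04)
  r3 <- blandAltman(x3, y)
  expect_equal(r3@meanDiff, 0.01)
  expect_equal(r3@sdDiff, 0.02160247, tolerance = 1e-6)
  expect_equal(r3@loaLower, -0.03234084, tolerance = 1e-6)
  expect_equal(r3@loaUpper, 0.05234084, tolerance = 1e-6)
  expect_equal(r3@loaUpper - r3@loaLower, 2 * 1.96 * r3@sdDiff)

  expect_error(blandAltman(1:2 / 10, 1:3 / 10), "equal length")
  expect_error(blandAltman(c(.1, .2, .3), c(.1, .2, .3),
                           sample_ids_x = c("a", "b", "c"),
                           sample_ids_y = c("a", "b", "d")),
               "unpaired")
})

test_that("swapping platforms negates the mean difference and keeps the SD", {
  set.seed(31)
  x <- runif(40, .2, .8); y <- x + rnorm(40, 0.01, 0.03)
  rxy <- blandAltman(x, y); ryx <- blandAltman(y, x)
  expect_equal(rxy@meanDiff, -ryx@meanDiff)
  expect_equal(rxy@sdDiff, ryx@sdDiff)
})

test_that("computed LoA bracket about 95% of Gaussian differences", {
  set.seed(77)
  y <- runif(5000, .2, .8)
  x <- y + rnorm(5000, 0.01, 0.03)
  r <- blandAltman(x, y)
  inside <- mean(r@diffs >= r@loaLower & r@diffs <= r@loaUpper)
  expect_gte(inside, 0.935)
  expect_lte(inside, 0.965)
})

test_that("normality testing is calibrated and detects gross non-normality", {
  expect_error(testNormality(c(0.1, 0.2)), "3 <= n")
  expect_error(testNormality(rep(0.1, 10)), "constant")
  set.seed(41)
  null_p <- replicate(200, testNormality(rnorm(500, 0, 0.03))$p)
  expect_gte(mean(null_p > 0.01), 0.95)
  bimodal_p <- replicate(200, {
    testNormality(c(rnorm(250, -0.1, 0.01), rnorm(250, 0.1, 0.01)))$p
  })
  expect_gte(mean(bimodal_p < 0.01), 0.95)
})

test_that("uniformity regression matches the OLS oracle and handles degeneracy", {
  means <- c(0.2, 0.4, 0.6, 0.8)
  # constant differences: exact zero slope, uniform by convention
  suppressMessages(u0 <- testUniformity(diffs = rep(0.02, 4), means = means))
  expect_equal(u0$slope, 0)
  expect_equal(u0$p, 1)
  expect_true(u0$uniform && u0$degenerate)
  # perfect trend: fails by convention
  suppressMessages(u1 <- testUniformity(diffs = 0.1 * means, means = means))
  expect_equal(u1$p, 0)
  expect_false(u1$uniform)
  # frozen OLS oracle: slope 0.07, two-sided slope t-test p 0.16334
  u2 <- testUniformity(diffs = c(0.00, 0.02, 0.01, 0.05), means = means)
  expect_equal(u2$slope, 0.07, tolerance = 1e-9)
  expect_equal(u2$p, 0.16333997, tolerance = 1e-6)
  expect_error(testUniformity(diffs = c(.1, .2, .3), means = rep(.5, 3)),
               "constant")
})

test_that("platform ANOVA matches hand computation and is calibrated", {
  g <- rep(c("A", "B"), each = 3)
  r <- anovaPlatforms(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  r2 <- anovaPlatforms(c(1, 2, 3, 4, 5, 6), g)
  expect_equal(r2$F, 13.5)
  expect_equal(r2$p, 0.02131164, tolerance = 1e-6)
  expect_false(r2$significant)  # alpha = 0.01 convention
  expect_error(anovaPlatforms(1:4, rep("A", 4)), "2 platform")
  expect_error(anovaPlatforms(1:3, c("A", "A", "B")), "n >= 2")

  set.seed(53)
  rej <- replicate(200, {
    anovaPlatforms(rnorm(60), rep(c("A", "B", "C"), each = 20))$significant
  })
  expect_lte(mean(rej), 0.04)  # binomial CI around the nominal 1%
})
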
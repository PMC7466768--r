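test_that("training harmonization applies the inclusive window and per-year cap", {
  b <- matrix(runif(71, .2, .8), 1, dimnames = list("CpG1", NULL))
  me <- makeME(b, age = 10:80)
  suppressMessages(h <- harmonizeTraining(me))
  expect_identical(ncol(h), 58L)           # 18..75 inclusive
  expect_identical(range(ages(h)), c(18, 75))

  # three samples in one year, cap two: reproducible random choice
  me3 <- makeME(matrix(runif(3, .2, .8), 1, dimnames = list("CpG1", NULL)),
                age = c(30, 30, 30))
  suppressMessages(h3a <- harmonizeTraining(me3, seed = 11))
  suppressMessages(h3b <- harmonizeTraining(me3, seed = 11))
  expect_identical(ncol(h3a), 2L)
  expect_identical(sampleIds(h3a), sampleIds(h3b))

  # duplicated cohort with cap one halves the data
  dup <- makeME(matrix(runif(20, .2, .8), 1, dimnames = list("CpG1", NULL)),
                age = rep(41:50, 2))
  suppressMessages(h1 <- harmonizeTraining(dup, max_per_year = 1))
  expect_identical(ncol(h1), 10L)

  expect_error(harmonizeTraining(makeME(matrix(.5, 1, dimnames =
    list("CpG1", NULL)), age = 5)), "age window")
})

test_that("harmonization is idempotent", {
  set.seed(9)
  me <- makeME(matrix(runif(120, .2, .8), 1, dimnames = list("CpG1", NULL)),
               age = sample(10:90, 120, replace = TRUE))
  suppressMessages(h1 <- harmonizeTraining(me, seed = 4))
  suppressMessages(h2 <- harmonizeTraining(h1, seed = 4))
  expect_identical(sampleIds(h1), sampleIds(h2))
  expect_equal(betas(h1), betas(h2))
})

test_that("z-scoring standardises exactly and is affine invariant", {
  b <- matrix(c(0.2, 0.4, 0.6), 1, dimnames = list("CpG1", NULL))
  me <- makeME(b, age = c(20, 40, 60))
  st <- zscoreFit(me)
  expect_equal(st$mean, 0.4)
  expect_equal(st$sd, 0.2)
  z <- zscoreApply(me, st)
  expect_equal(unname(betas(z)["CpG1", ]), c(-1, 0, 1))

  set.seed(15)
  big <- makeME(matrix(runif(3 * 50, .2, .8), nrow = 3,
                       dimnames = list(c("a", "b", "c"), NULL)),
                age = sample(18:75, 50, TRUE))
  zz <- betas(zscoreApply(big, zscoreFit(big)))
  expect_equal(unname(rowMeans(zz)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(zz, 1, sd)), rep(1, 3), tolerance = 1e-12)

  # affine platform bias a + c * beta leaves z-scores unchanged
  biased <- makeME(0.05 + 0.9 * betas(big), age = ages(big),
                   platform = "other", sample_id = sampleIds(big))
  zb <- betas(zscoreApply(biased, zscoreFit(biased)))
  expect_equal(unname(zb), unname(betas(zscoreApply(big, zscoreFit(big)))),
               tolerance = 1e-12)

  expect_error(zscoreFit(makeME(matrix(rep(.5, 3), 1,
    dimnames = list("flat", NULL)), age = c(20, 30, 40))), "flat")
})

test_that("a noiseless affine age law is recovered with zero-width intervals", {
  age <- 20:70
  b <- matrix((age - 20) / 60, 1, dimnames = list("CpG1", NULL))
  me <- makeME(b, age = age)
  m <- fitAgeModel(me, taus = c(0.1, 0.5, 0.9))
  for (f in m@fits)
    expect_equal(unname(coef(f)), c(20, 60), tolerance = 1e-7)
  p <- predictAge(m, me)
  expect_equal(p$point, as.numeric(age), tolerance = 1e-6)
  expect_equal(p$pi_upper - p$pi_lower, rep(0, 51), tolerance = 1e-6)
  expect_false(any(p$crossed))
})

test_that("q10-q90 intercept gap matches the Gaussian closed form", {
  set.seed(29)
  n <- 5000
  x <- matrix(runif(n, 0, 1), n, 1, dimnames = list(NULL, "CpG1"))
  y <- 20 + 50 * x[, 1] + rnorm(n, 0, 5)
  f10 <- fitQuantile(x, y, 0.1)
  f90 <- fitQuantile(x, y, 0.9)
  gap <- coef(f90)[["(Intercept)"]] - coef(f10)[["(Intercept)"]]
  expect_equal(gap, 2 * qnorm(0.9) * 5, tolerance = 0.05 * 12.81552)
})

test_that("prediction intervals achieve near-nominal 80% coverage", {
  tr <- defaultTrajectories()
  train <- simulateTrueBetas(cohortSpec(500, seed = 100), tr)
  test <- simulateTrueBetas(cohortSpec(500, seed = 101), tr)
  m <- fitAgeModel(train)
  p <- predictAge(m, test)
  cover <- mean(p$pi_lower <= p$age & p$age <= p$pi_upper)
  expect_gte(cover, 0.75)
  expect_lte(cover, 0.85)
})

test_that("constant models predict their intercept and crossing is resolved by swap", {
  me <- makeME(matrix(runif(10, .2, .8), 1, dimnames = list("CpG1", NULL)),
               age = rep(50, 10))
  m <- new("AgeModel", cpgIds = "CpG1", taus = c(0.1, 0.5, 0.9),
           fits = list(new("QRFit", tau = .1, coefficients = c(50, 0),
                           achievedLoss = 0),
                       new("QRFit", tau = .5, coefficients = c(50, 0),
                           achievedLoss = 0),
                       new("QRFit", tau = .9, coefficients = c(50, 0),
                           achievedLoss = 0)),
           zscored = FALSE, trainingMeta = list())
  p <- predictAge(m, me)
  expect_equal(p$point, rep(50, 10))
  expect_equal(p$pi_lower, p$pi_upper)

  # force crossed quantiles: lower fit above upper fit
  m@fits[[1]]@coefficients <- c(60, 0)
  suppressMessages(p2 <- predictAge(m, me))
  expect_true(all(p2$crossed))
  expect_true(all(p2$pi_lower <= p2$pi_upper))
})

test_that("training sets pool by concatenation with matching panels", {
  tr <- defaultTrajectories()
  d1 <- applyPlatform(simulateTrueBetas(cohortSpec(116, seed = 1), tr),
                      platformSpec("EpiTYPER"), seed = 1)
  d2 <- applyPlatform(simulateTrueBetas(cohortSpec(106, seed = 2), tr),
                      platformSpec("pyrosequencing"), seed = 2)
  d3 <- applyPlatform(simulateTrueBetas(cohortSpec(100, seed = 3), tr),
                      platformSpec("MiSeq"), seed = 3)
  pooled <- combineTraining(list(d1, d2, d3))
  expect_identical(ncol(pooled), 322L)
  expect_setequal(unique(platforms(pooled)),
                  c("EpiTYPER", "pyrosequencing", "MiSeq"))
  expect_identical(combineTraining(list(d1)), d1)
  d4 <- d3[1:2, ]
  expect_error(combineTraining(list(d1, d4)), "panels differ")
})

test_that("z-scored cross-platform prediction matches same-platform prediction under affine bias", {
  tr <- defaultTrajectories()
  truth_train <- simulateTrueBetas(cohortSpec(300, seed = 61), tr)
  truth_test <- simulateTrueBetas(cohortSpec(200, seed = 62), tr)
  plA <- platformSpec("A")
  plB <- platformSpec("B", affine_offset = 0.08, affine_scale = 0.9)
  trainA <- applyPlatform(truth_train, plA, seed = 1)
  testA <- applyPlatform(truth_test, plA, seed = 2)
  testB <- applyPlatform(truth_test, plB, seed = 3)
  m <- fitAgeModel(trainA, zscore = TRUE)
  pA <- predictAge(m, testA)
  pB <- predictAge(m, testB)
  # noiseless affine bias: self-standardised z-scores are identical,
  # so the predictions agree exactly
  expect_equal(pB$point, pA$point, tolerance = 1e-9)
  expect_equal(pB$pi_lower, pA$pi_lower, tolerance = 1e-9)
})
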
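test_that("noiseless trajectories evaluate linearly and clip at the boundaries", {
  co <- cohortSpec(1, age_min = 50, age_max = 50, seed = 1)
  me <- simulateTrueBetas(co, list(trajectorySpec("A", 0.1, 0.004)))
  expect_equal(unname(betas(me)["A", ]), 0.3)
  expect_identical(unique(platforms(me)), "truth")

  co2 <- cohortSpec(1, age_min = 100, age_max = 100, seed = 1)
  me2 <- simulateTrueBetas(co2, list(trajectorySpec("A", 0.5, 0.02)))
  expect_equal(unname(betas(me2)["A", ]), 1.0)

  expect_error(simulateTrueBetas(co, list()), "TrajectorySpec")
})

test_that("biological noise has the generating SD", {
  co <- cohortSpec(1000, age_min = 40, age_max = 40, seed = 11)
  me <- simulateTrueBetas(co, list(trajectorySpec("A", 0.3, 0.002,
                                                  bio_sd = 0.03)))
  dev <- betas(me)["A", ] - (0.3 + 0.002 * 40)
  expect_equal(sd(dev), 0.03, tolerance = 0.1)
})

test_that("cohort age sampling honours the design", {
  one <- simulateTrueBetas(cohortSpec(58, 18, 75, "one_per_year", seed = 2),
                           defaultTrajectories())
  expect_identical(sort(ages(one)), as.numeric(18:75))
  # cycling: 116 samples over 58 years gives exactly two per year
  two <- simulateTrueBetas(cohortSpec(116, 18, 75, "one_per_year", seed = 2),
                           defaultTrajectories())
  expect_true(all(table(ages(two)) == 2L))
  unif <- simulateTrueBetas(cohortSpec(200, 18, 75, "uniform", seed = 2),
                            defaultTrajectories())
  expect_true(all(ages(unif) >= 18 & ages(unif) <= 75))
})

test_that("dye-gain distortion follows the peak-ratio closed form", {
  expect_equal(dyeGainDistortion(0.5, 3), 0.75)
  expect_equal(dyeGainDistortion(c(0, 1), 3), c(0, 1))
  expect_error(dyeGainDistortion(0.5, 0), "gain")
  # strictly increasing in beta for several gains
  b <- seq(0, 1, by = 0.01)
  for (g in c(0.3, 1, 1.6, 5)) {
    expect_true(all(diff(dyeGainDistortion(b, g)) > 0))
  }
  # maximal distortion is attained in the interior of [0, 1]
  for (g in c(0.4, 2, 5)) {
    dist <- abs(dyeGainDistortion(b, g) - b)
    expect_gt(which.max(dist), 1)
    expect_lt(which.max(dist), length(b))
  }
})

test_that("the identity platform is a no-op and platforms are seed-reproducible", {
  truth <- simulateTrueBetas(cohortSpec(25, seed = 3), defaultTrajectories())
  ident <- platformSpec("ident")
  out <- applyPlatform(truth, ident, seed = 99)
  expect_equal(unname(betas(out)), unname(betas(truth)))

  snap <- defaultPlatforms()$SNaPshot
  a <- applyPlatform(truth, snap, seed = 7)
  b <- applyPlatform(truth, snap, seed = 7)
  expect_identical(betas(a), betas(b))
  expect_identical(ncol(a), 2L * ncol(truth))  # duplicate measurements
  c2 <- applyPlatform(truth, snap, seed = 8)
  expect_false(identical(betas(a), betas(c2)))
})

test_that("gain formula is applied per CpG on the matrix path", {
  b <- matrix(c(0.5, 0.5), nrow = 2, dimnames = list(c("A", "B"), "s1"))
  me <- MethylationExperiment(b, age = 40, platform = "truth",
                              sample_id = "s1")
  pl <- platformSpec("gainy", dye_gain = c(A = 3))
  out <- applyPlatform(me, pl, seed = 1)
  expect_equal(unname(betas(out)["A", ]), 0.75)
  expect_equal(unname(betas(out)["B", ]), 0.5)
})

test_that("noiseless pipelines are deterministic whatever the seed", {
  tr <- list(trajectorySpec("A", 0.2, 0.005, bio_sd = 0))
  co1 <- cohortSpec(20, 20, 60, "one_per_year", seed = 1)
  co2 <- cohortSpec(20, 20, 60, "one_per_year", seed = 999)
  pl <- platformSpec("P", affine_offset = 0.05)
  a <- applyPlatform(simulateTrueBetas(co1, tr), pl, seed = 1)
  b <- applyPlatform(simulateTrueBetas(co2, tr), pl, seed = 42)
  expect_equal(betas(a), betas(b))
})
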
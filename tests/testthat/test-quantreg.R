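test_that("pinball loss follows the check-function definition", {
  expect_equal(pinballLoss(c(1, -1), 0.5), 1.0)
  expect_equal(pinballLoss(2, 0.9), 1.8)
  expect_equal(pinballLoss(-2, 0.9), 0.2)
  expect_equal(pinballLoss(numeric(0), 0.3), 0)
  expect_error(pinballLoss(1, 1), "tau")
})

test_that("exact affine data are interpolated with zero loss at any tau", {
  set.seed(13)
  x <- matrix(runif(40), 20, 2)
  y <- 20 + 60 * x[, 1] - 15 * x[, 2]
  for (tau in c(0.1, 0.5, 0.9)) {
    f <- fitQuantile(x, y, tau)
    expect_equal(achievedLoss(f), 0, tolerance = 1e-9)
    expect_equal(unname(coef(f)), c(20, 60, -15), tolerance = 1e-8)
    expect_equal(predict(f, x), y, tolerance = 1e-8)
  }
})

test_that("the three-point median line attains the enumerated optimum", {
  x <- matrix(c(0, 1, 2), 3, 1)
  y <- c(0, 1, 4)
  f <- fitQuantile(x, y, 0.5)
  # candidate lines through 2 of the 3 points have losses 1, 0.5, 1
  expect_equal(achievedLoss(f), 0.5, tolerance = 1e-10)
  expect_equal(achievedLoss(f), oracleQuantileLoss(x, y, 0.5),
               tolerance = 1e-10)
})

test_that("achieved loss matches the subset-enumeration oracle on 200 random instances", {
  set.seed(97)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    p <- sample(1:2, 1)
    x <- matrix(runif(n * p), n, p)
    if (qr(cbind(1, x))$rank < p + 1) next
    y <- runif(n, 0, 100)
    tau <- sample(c(0.1, 0.25, 0.5, 0.75, 0.9), 1)
    f <- fitQuantile(x, y, tau)
    expect_lt(abs(achievedLoss(f) - oracleQuantileLoss(x, y, tau)), 1e-8)
  }
})

test_that("fits are equivariant to scaling and shifting the response", {
  set.seed(23)
  x <- matrix(runif(30), 15, 2)
  y <- 5 + 20 * x[, 1] + rnorm(15)
  f <- fitQuantile(x, y, 0.25)
  fs <- fitQuantile(x, 3 * y, 0.25)
  expect_equal(achievedLoss(fs), 3 * achievedLoss(f), tolerance = 1e-7)
  expect_equal(unname(coef(fs)), 3 * unname(coef(f)), tolerance = 1e-6)
  fsh <- fitQuantile(x, y + 7, 0.25)
  expect_equal(unname(coef(fsh)) - c(7, 0, 0), unname(coef(f)),
               tolerance = 1e-6)
  expect_equal(achievedLoss(fsh), achievedLoss(f), tolerance = 1e-7)
})

test_that("an intercept-only median fit returns a median of y", {
  y <- c(3, 9, 1, 7, 5)  # odd n: unique sample median
  f <- fitQuantile(matrix(numeric(0), 5, 0), y, 0.5)
  expect_equal(unname(coef(f)), median(y))
  expect_equal(achievedLoss(f), pinballLoss(y - median(y), 0.5))
})

test_that("input validation rejects bad designs", {
  x <- matrix(runif(10), 5, 2)
  expect_error(fitQuantile(x, runif(4), 0.5), "length")
  expect_error(fitQuantile(x[, c(1, 1)], runif(5), 0.5), "collinear")
  expect_error(fitQuantile(x[1:3, ], runif(3), 0.5), "n > p")
  xna <- x; xna[1] <- NA
  expect_error(fitQuantile(xna, runif(5), 0.5), "missing")
  f <- fitQuantile(x, runif(5), 0.5)
  expect_error(predict(f, matrix(1, 2, 3)), "predictor")
})

test_that("large-sample fits recover the true conditional quantile line", {
  set.seed(71)
  n <- 10000
  x <- matrix(runif(n), n, 1)
  y <- 10 + 5 * x[, 1] + rnorm(n)
  f <- fitQuantile(x, y, 0.9)
  truth <- c(10 + qnorm(0.9), 5)
  expect_equal(unname(coef(f)), truth, tolerance = 0.02 * max(abs(truth)))
})
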
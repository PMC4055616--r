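# Reduced major-axis regression and its bootstrap.

test_that("RMA slope, intercept and r match hand computation", {
  fit <- rmaFit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(coef(fit), c(intercept = 0, slope = 2))
  expect_equal(pearsonR(fit), 1)

  fit2 <- rmaFit(c(0, 1, 2), c(0, 1, 3))
  expect_equal(fit2@slope, sqrt(7 / 3), tolerance = 1e-6)    # 1.52753
  expect_equal(fit2@slope, 1.5275, tolerance = 1e-4)
  expect_equal(fit2@intercept, 4 / 3 - sqrt(7 / 3), tolerance = 1e-6)  # -0.1942
  expect_equal(fit2@pearson_r, 1.5 / sqrt(7 / 3), tolerance = 1e-6)    # 0.9820
  expect_equal(nobs(fit2), 3L)
})

test_that("RMA slope equals the brute-force product-of-deviations minimiser", {
  withSeed(11, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      x <- rnorm(n)
      y <- sample(c(-1, 1), 1) * x + rnorm(n, sd = runif(1, 0.1, 2))
      expect_equal(rmaFit(x, y)@slope, rmaSlopeBrute(x, y), tolerance = 1e-4)
    }
  })
})

test_that("RMA identities hold on random data", {
  withSeed(7, {
    for (i in 1:50) {
      n <- sample(4:60, 1)
      x <- rnorm(n, sd = runif(1, 0.5, 3))
      y <- 0.8 * x + rnorm(n, sd = runif(1, 0.2, 2))
      fit <- rmaFit(x, y)
      # |slope| = sd(y)/sd(x), sign follows r
      expect_equal(abs(fit@slope), sd(y) / sd(x))
      expect_equal(sign(fit@slope), sign(fit@pearson_r))
      # geometric mean of OLS(y|x) slope and 1/OLS(x|y) slope
      b_yx <- coef(lm(y ~ x))[[2]]
      b_xy <- coef(lm(x ~ y))[[2]]
      expect_equal(abs(fit@slope), sqrt(abs(b_yx / b_xy)), tolerance = 1e-10)
      # duality: slope(x,y) * slope(y,x) = 1 in magnitude
      expect_equal(abs(fit@slope * rmaFit(y, x)@slope), 1, tolerance = 1e-10)
      # affine equivariance
      a <- runif(1, 0.5, 3); cc <- runif(1, 0.5, 3)
      fit2 <- rmaFit(a * x + 1, cc * y - 2)
      expect_equal(fit2@slope, (cc / a) * fit@slope, tolerance = 1e-10)
    }
  })
})

test_that("degenerate data raise a degenerate-data error", {
  expect_error(rmaFit(c(1, 1, 1), c(1, 2, 3)), class = "phytoDegenerateError")
  expect_error(rmaFit(c(1, 2, 3), c(2, 2, 2)), class = "phytoDegenerateError")
  expect_error(rmaFit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("bootstrap CI collapses on collinear data and brackets the estimate", {
  x <- c(1, 2, 3, 4, 5)
  fit <- bootstrapRmaCi(x, 2 * x, n_boot = 200, seed = 3)
  expect_equal(slopeCI(fit), c(2, 2))
  expect_equal(interceptCI(fit), c(0, 0))
  withSeed(5, {
    x <- rnorm(40)
    y <- x + rnorm(40, sd = 0.5)
    f <- bootstrapRmaCi(x, y, n_boot = 500, seed = 9)
    expect_true(slopeCI(f)[1] <= f@slope && f@slope <= slopeCI(f)[2])
    expect_true(interceptCI(f)[1] <= f@intercept &&
                f@intercept <= interceptCI(f)[2])
  })
})

test_that("bootstrap is deterministic for a fixed seed and leaves the RNG alone", {
  withSeed(21, {
    x <- rnorm(30); y <- 1.3 * x + rnorm(30, sd = 0.4)
  })
  f1 <- bootstrapRmaCi(x, y, n_boot = 300, seed = 42)
  set.seed(1); before <- rnorm(1)
  set.seed(1)
  f2 <- bootstrapRmaCi(x, y, n_boot = 300, seed = 42)
  after <- rnorm(1)
  expect_identical(slopeCI(f1), slopeCI(f2))
  expect_identical(interceptCI(f1), interceptCI(f2))
  expect_identical(before, after)  # caller's stream untouched
  f3 <- bootstrapRmaCi(x, y, n_boot = 300, seed = 43)
  expect_false(identical(slopeCI(f1), slopeCI(f3)))
})

test_that("mostly-constant data trip the instability guard", {
  # 3 distinct-x cases among 4: resamples collapse to zero variance often
  x <- c(1, 1, 1, 2)
  y <- c(1, 1, 1, 3)
  expect_error(bootstrapRmaCi(x, y, n_boot = 200, seed = 1),
               class = "phytoInstabilityError")
})

test_that("CI width shrinks roughly as 1/sqrt(n) on nested subsamples", {
  withSeed(31, {
    x <- rnorm(640); y <- x + rnorm(640, sd = 0.6)
  })
  w <- vapply(c(40, 160, 640), function(n) {
    f <- bootstrapRmaCi(x[1:n], y[1:n], n_boot = 400, seed = 2)
    diff(slopeCI(f))
  }, numeric(1))
  expect_true(all(diff(w) < 0))
  # quadrupling n should roughly halve the width (allow generous slack)
  expect_equal(w[1] / w[2], 2, tolerance = 0.5)
  expect_equal(w[2] / w[3], 2, tolerance = 0.5)
})

test_that("BCa intervals are available and close to percentile on clean data", {
  withSeed(13, {
    x <- rnorm(60); y <- x + rnorm(60, sd = 0.5)
  })
  fp <- bootstrapRmaCi(x, y, n_boot = 500, seed = 4)
  fb <- bootstrapRmaCi(x, y, n_boot = 500, seed = 4, method = "bca")
  expect_equal(fb@method, "bca")
  expect_equal(slopeCI(fb), slopeCI(fp), tolerance = 0.15)
})
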
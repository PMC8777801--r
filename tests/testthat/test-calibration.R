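# Monte Carlo calibration of the expected-fidelity curve and the
# multistart weighted least-squares fit.

test_that("calibration grid is the three-part union with junctions deduplicated", {
  g <- calibrationGrid()
  expect_length(g, 1385)
  expect_equal(g[1:3], c(0, 0.01, 0.02))
  expect_equal(sum(g == 6), 1)
  expect_equal(sum(g == 66), 1)
  expect_equal(max(g), 250)
  expect_true(!is.unsorted(g, strictly = TRUE))
})

test_that("single-point simulation is exact at zero and unbiased elsewhere", {
  expect_equal(simulatePoint(0, 100, seed = 1), list(mean = 0, variance = 0))
  expect_error(simulatePoint(1, 1), "at least 2")
  or1 <- bruteDeltaE(1)
  p1 <- simulatePoint(1, 2e5, seed = 7)
  expect_equal(p1$mean, or1$mean, tolerance = 4 * sqrt(p1$variance / 2e5) / or1$mean)
  expect_equal(p1$variance, or1$variance, tolerance = 0.05)
  # large-lambda mean matches the three-term series truncation
  p100 <- simulatePoint(100, 2e5, seed = 8)
  expect_equal(p100$mean, 0.5 + 1 / 1200 + 1 / 120000,
               tolerance = 4 * sqrt(p100$variance / 2e5))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulatePoint(2.5, 5e4, seed = 42)
  b <- simulatePoint(2.5, 5e4, seed = 42)
  expect_identical(a, b)
  t1 <- simulateCalibration(c(0, 0.5, 2, 10), S = 2e4, seed = 9)
  t2 <- simulateCalibration(c(0, 0.5, 2, 10), S = 2e4, seed = 9)
  expect_identical(calibrationData(t1), calibrationData(t2))
})

test_that("standardized sample means have unit-scale spread (CLT sanity)", {
  oracle <- bruteDeltaE(1)
  S <- 1e4
  z <- vapply(1:50, function(r) {
    p <- simulatePoint(1, S, seed = 100 + r)
    (p$mean - oracle$mean) / sqrt(p$variance / S)
  }, numeric(1))
  expect_gt(sd(z), 0.7)
  expect_lt(sd(z), 1.3)
})

test_that("calibration tables round trip through CSV", {
  tab <- simulateCalibration(c(0, 1, 3, 8, 20), S = 1e4, seed = 5)
  f <- tempfile(fileext = ".csv")
  writeCalibration(tab, f)
  back <- readCalibration(f)
  expect_equal(calibrationData(back), calibrationData(tab))
  expect_identical(back@samples, tab@samples)
  expect_identical(back@seed, tab@seed)
})

# build a synthetic table whose means are exactly 1/2 + eps(lambda; cStar)
# plus optional Gaussian noise of sd sqrt(v/S)
syntheticTable <- function(cStar, S = 1e6, noise = TRUE, seed = 1) {
  lam <- calibrationGrid()
  lam <- lam[lam > 0]
  lam <- lam[seq(1, length(lam), by = 4)]   # thin for speed
  p <- fitParams(cStar)
  mu <- 0.5 + epsilonCorrection(lam, p)
  v <- vapply(lam, function(l) bruteDeltaE(l)$variance, numeric(1))
  set.seed(seed)
  means <- if (noise) mu + rnorm(length(lam), 0, sqrt(v / S)) else mu
  new("CalibrationTable", lambdas = lam, means = pmax(means, 0), variances = v,
      samples = as.integer(S), seed = as.integer(seed))
}

test_that("weighted fit recovers known parameters from a synthetic table", {
  cStar <- c(2, -1, -5, 15)
  tab <- syntheticTable(cStar, S = 1e6, noise = TRUE, seed = 13)
  fit <- fitCorrection(tab, nStarts = 40L, seed = 13)
  expect_equal(unname(fitCoef(fit@params)), cStar, tolerance = 0.05)
  # zero-noise consistency: cost ~ 0 and recovery to solver tolerance
  tab0 <- syntheticTable(cStar, noise = FALSE)
  fit0 <- fitCorrection(tab0, nStarts = 40L, seed = 14)
  expect_lt(fit0@cost, 1e-10)
  expect_equal(unname(fitCoef(fit0@params)), cStar, tolerance = 1e-4)
})

test_that("fit is invariant to rescaling all weights by a positive constant", {
  cStar <- c(2, -1, -5, 15)
  tab <- syntheticTable(cStar, S = 1e6, noise = TRUE, seed = 17)
  scaled <- new("CalibrationTable", lambdas = tab@lambdas, means = tab@means,
                variances = tab@variances * 7.3, samples = tab@samples,
                seed = tab@seed)
  f1 <- fitCorrection(tab, nStarts = 15L, seed = 3)
  f2 <- fitCorrection(scaled, nStarts = 15L, seed = 3)
  expect_equal(fitCoef(f1@params), fitCoef(f2@params), tolerance = 1e-5)
})

test_that("percentage error curve behaves as the definitions require", {
  tab <- simulateCalibration(c(0, 0.2, 1, 2, 4, 10), S = 2e5, seed = 23)
  # the table means against themselves: identically zero
  self <- percentageErrorCurve(tab, tab@means)
  expect_equal(self$error, rep(0, nrow(self)))
  # lambda = 0 is excluded
  expect_false(0 %in% self$lambda)
  # constant 1/2: large positive error as lambda -> 0 (means -> 0)
  cst <- percentageErrorCurve(tab, 0.5)
  expect_gt(cst$error[cst$lambda == 0.2], 25)
  # at lambda = 2 the constant is off by 5-15 percent, negative
  e2 <- cst$error[cst$lambda == 2]
  expect_lt(e2, -5)
  expect_gt(e2, -15)
})
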
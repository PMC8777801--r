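# Exact Poisson central moments, moment-ratio polynomials, and the
# truncated series expansion of the expected KL fidelity.

test_that("central moments reproduce the known low-order polynomials", {
  expect_equal(polyCoefficients(centralMoment(1))$value, 0)
  expect_equal(polyCoefficients(centralMoment(2))$value, c(0, 1))   # lambda
  expect_equal(polyCoefficients(centralMoment(4))$value, c(0, 1, 3))# lambda + 3 lambda^2
  expect_error(centralMoment(0), "i must be")
})

test_that("central moments agree with the truncated-pmf oracle", {
  for (i in c(3, 5, 6, 8)) {
    eta <- centralMoment(i)
    for (lambda in c(0.25, 1, 4)) {
      expect_equal(evalPoly(eta, lambda), bruteCentralMoment(i, lambda),
                   tolerance = 1e-10)
    }
  }
})

test_that("moment-ratio polynomials match the published table verbatim", {
  expected <- list(
    `0` = 1, `1` = 1, `2` = c(1, 3), `3` = c(1, 10),
    `4` = c(1, 25, 15), `5` = c(1, 56, 105),
    `6` = c(1, 119, 490, 105), `7` = c(1, 246, 1918, 1260))
  for (i in 0:7) {
    p <- momentRatioPoly(i)
    co <- polyCoefficients(p)
    expect_equal(co$num, expected[[as.character(i)]])
    expect_true(all(co$den == 1))
  }
})

test_that("moment-ratio polynomials have degree floor(i/2) and unit constant", {
  for (i in 0:11) {
    p <- momentRatioPoly(i)
    expect_identical(polyDegree(p), as.integer(floor(i / 2)))
    expect_equal(polyCoefficients(p)$value[1], 1)
  }
})

test_that("series coefficients reproduce the exact rational rows", {
  # frozen exact rationals, independently computed by symbolic expansion
  rows <- list(
    `1` = rbind(c(1, 1)),
    `2` = rbind(c(1, 2), c(-1, 2)),
    `3` = rbind(c(1, 2), c(5, 6), c(1, 3)),
    `4` = rbind(c(1, 2), c(1, 12), c(-29, 12), c(-1, 4)),
    `5` = rbind(c(1, 2), c(1, 12), c(31, 12), c(99, 20), c(1, 5)),
    `6` = rbind(c(1, 2), c(1, 12), c(1, 12), c(-1003, 60), c(-93, 10), c(-1, 6)),
    `7` = rbind(c(1, 2), c(1, 12), c(1, 12), c(797, 60), c(687, 10),
                c(713, 42), c(1, 7)),
    `8` = rbind(c(1, 2), c(1, 12), c(1, 12), c(19, 120), c(-3001, 20),
                c(-39925, 168), c(-1721, 56), c(-1, 8)),
    `9` = rbind(c(1, 2), c(1, 12), c(1, 12), c(19, 120), c(1899, 20),
                c(516833, 504), c(126829, 168), c(4007, 72), c(1, 9)))
  for (N in 1:9) {
    g <- seriesGamma(seriesCoefficients(N))
    expect_equal(cbind(g$num, g$den), unname(rows[[as.character(N)]]),
                 ignore_attr = TRUE, label = paste("order", N))
  }
})

test_that("series order cap and weights behave as specified", {
  expect_error(seriesCoefficients(13), "unsupported truncation order")
  expect_silent(seriesCoefficients(13, cap = 13))
  om <- seriesOmega(seriesCoefficients(5))
  expect_equal(om$value[1:4], (-1)^(0:3) / ((1:4) * (2:5)))
  expect_equal(om$value[5], (-1)^4 / 5)
})

test_that("gamma coefficients stabilize once the order passes 2i + 2", {
  # gamma_i receives contributions from moment-ratio terms up to index 2i,
  # plus the special last series weight, so it is final for all N >= 2i+2
  cap <- 12L
  gAll <- lapply(1:cap, function(N) seriesGamma(seriesCoefficients(N, cap = cap)))
  for (i in 0:5) {
    vals <- vapply((2 * i + 2):cap, function(N) gAll[[N]]$value[i + 1], numeric(1))
    expect_equal(vals, rep(vals[1], length(vals)),
                 label = sprintf("gamma_%d for N >= %d", i, 2 * i + 2))
  }
  # and the limiting values of the first few coefficients are positive and
  # strictly increasing from i = 2 on (low-lambda divergence of the series)
  lim <- vapply(0:5, function(i) gAll[[2 * i + 2]]$value[i + 1], numeric(1))
  expect_true(all(lim[3:6] > 0))
  expect_true(all(diff(lim[3:6]) > 0))
})

test_that("truncated expected value evaluates the series at lambda^-i", {
  expect_equal(truncatedExpectedValue(0.7, 1), 1)
  expect_equal(truncatedExpectedValue(2, 2), 0.25)   # 1/2 - 1/(2*2)
  g <- seriesGamma(seriesCoefficients(9))
  expect_equal(truncatedExpectedValue(1, 9), sum(g$value))
  expect_error(truncatedExpectedValue(-1, 3), "positive")
})

test_that("convergence diagnostic is an eventually increasing probability tending to 1", {
  expect_equal(convergenceProbability(0.4), 0)               # floor(2*0.4) = 0
  expect_equal(convergenceProbability(1), exp(-1) * (1 + 1 / 2))
  expect_gte(convergenceProbability(200), 0.999)
  lam <- seq(5, 300, by = 2.5)
  p <- convergenceProbability(lam)
  expect_true(all(diff(p) > -1e-12))
  expect_true(all(p >= 0 & p <= 1))
})
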
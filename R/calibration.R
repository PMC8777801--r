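## Monte Carlo estimation of the expected KL fidelity delta^(E)(lambda)
## and the multistart weighted least-squares fit of the rational
## correction model.

#' Standard calibration grid of Poisson means
#'
#' The three-part grid used for calibrating the expected-fidelity curve:
#' dense where the curve bends (steps of 0.01 on \eqn{[0, 6]}), coarser on
#' \eqn{[6, 66]} (steps of 0.1) and on \eqn{[66, 250]} (steps of 1), with
#' the duplicated junction points removed — 1385 values in total.
#'
#' @return Increasing numeric vector of length 1385 starting at 0.
#' @export
calibrationGrid <- function() {
  g <- c(seq(0, 6, by = 0.01), seq(6, 66, by = 0.1), seq(66, 250, by = 1))
  sort(unique(round(g, 2)))
}

#' Monte Carlo estimate of the expected KL fidelity at one Poisson mean
#'
#' Draws \eqn{S} Poisson(\eqn{\lambda}) variates, maps them through the
#' per-pixel fidelity \eqn{F(\cdot)} (with the \eqn{\lambda} of the draw
#' as the expected count), and returns the sample mean and unbiased sample
#' variance of the \eqn{S} fidelity values.  Internally the draws are
#' tabulated so \eqn{F} is evaluated once per distinct count, which makes
#' large \eqn{S} cheap.
#'
#' @param lambda non-negative Poisson mean.
#' @param S number of samples, \eqn{\ge 2}.
#' @param seed integer seed; the result is reproducible bit-for-bit.
#' @return \code{list(mean =, variance =)}.
#' @export
simulatePoint <- function(lambda, S, seed = 1L) {
  if (length(lambda) != 1 || lambda < 0) stop("lambda must be a non-negative scalar", call. = FALSE)
  if (S < 2) stop("S must be at least 2 (variance undefined otherwise)", call. = FALSE)
  set.seed(seed)
  .simulatePointStream(lambda, S)
}

## draws from the current RNG stream (no re-seeding)
.simulatePointStream <- function(lambda, S) {
  if (lambda == 0) return(list(mean = 0, variance = 0))
  y <- stats::rpois(S, lambda)
  counts <- tabulate(y + 1L)
  vals <- seq_along(counts) - 1L
  keep <- counts > 0L
  counts <- counts[keep]; vals <- vals[keep]
  f <- klTerm(rep(lambda, length(vals)), vals)
  m <- sum(counts * f) / S
  v <- sum(counts * (f - m)^2) / (S - 1)
  list(mean = m, variance = v)
}

#' Monte Carlo calibration table of the expected KL fidelity
#'
#' Per-\eqn{\lambda} sample means \eqn{\hat\delta^{(E)}(\lambda_i)} and
#' unbiased variances \eqn{v_i} of the per-pixel KL fidelity
#' \eqn{F(Y_{\lambda_i})}, estimated from \eqn{S} Poisson draws per grid
#' point.  At \eqn{\lambda = 0} the fidelity is identically zero, so mean
#' and variance are exactly 0 there (that point is excluded from the
#' weighted fit).
#'
#' @slot lambdas increasing non-negative grid.
#' @slot means sample means of the fidelity.
#' @slot variances unbiased sample variances.
#' @slot samples number of draws per point.
#' @slot seed RNG seed used.
#' @seealso [simulateCalibration()], [fitCorrection()]
#' @export
setClass("CalibrationTable",
         representation(lambdas = "numeric", means = "numeric",
                        variances = "numeric", samples = "integer",
                        seed = "integer"))

setValidity("CalibrationTable", function(object) {
  n <- length(object@lambdas)
  if (length(object@means) != n || length(object@variances) != n)
    return("lambdas, means, variances must have equal length")
  if (is.unsorted(object@lambdas, strictly = TRUE)) return("lambdas must be strictly increasing")
  if (any(object@lambdas < 0)) return("lambdas must be non-negative")
  if (any(object@means < 0)) return("means must be non-negative")
  if (any(object@variances < 0)) return("variances must be non-negative")
  if (any(object@variances[object@lambdas > 0] == 0))
    return("variance must be positive at lambda > 0")
  TRUE
})

setMethod("show", "CalibrationTable", function(object) {
  cat("CalibrationTable:", length(object@lambdas), "lambda points in [",
      min(object@lambdas), ",", max(object@lambdas), "], S =",
      object@samples, ", seed =", object@seed, "\n")
})

#' @describeIn CalibrationTable-class simulate a table on a grid.
#' @param lambdas grid of Poisson means (default [calibrationGrid()]).
#' @param S samples per point.
#' @param seed integer seed governing the whole simulation.
#' @export
simulateCalibration <- function(lambdas = calibrationGrid(), S = 1e6, seed = 1L) {
  lambdas <- sort(unique(as.numeric(lambdas)))
  set.seed(seed)
  means <- numeric(length(lambdas)); vars <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    r <- .simulatePointStream(lambdas[i], S)
    means[i] <- r$mean; vars[i] <- r$variance
  }
  new("CalibrationTable", lambdas = lambdas, means = means, variances = vars,
      samples = as.integer(S), seed = as.integer(seed))
}

#' @describeIn CalibrationTable-class as a data.frame
#'   (\code{lambda}, \code{mean}, \code{variance}).
#' @param table a \code{CalibrationTable}.
#' @export
calibrationData <- function(table) {
  stopifnot(is(table, "CalibrationTable"))
  data.frame(lambda = table@lambdas, mean = table@means,
             variance = table@variances)
}

#' @describeIn CalibrationTable-class write / read as CSV (the sample
#'   size and seed travel in a comment header line).
#' @param path CSV file path.
#' @export
writeCalibration <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# samples=%d seed=%d", table@samples, table@seed), con)
  utils::write.csv(calibrationData(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  d <- utils::read.csv(path, comment.char = "#")
  new("CalibrationTable", lambdas = d$lambda, means = d$mean,
      variances = d$variance, samples = meta[1], seed = meta[2])
}

## weighted residuals for the least-squares problem; non-finite values
## (denominator near a sign change) are replaced by a large penalty so the
## optimizer retreats instead of crashing
.fitResiduals <- function(cvec, lambda, d, sqrtw) {
  den <- 12 * lambda^3 + cvec[3] * lambda^2 + cvec[4] * lambda - 2 * cvec[2]
  eps <- (lambda^2 + cvec[1] * lambda + cvec[2]) / den
  r <- sqrtw * (d - eps)
  bad <- !is.finite(r) | den <= 0
  r[bad] <- 1e6
  r
}

#' Fit the rational correction model to a calibration table
#'
#' Minimizes the weighted least-squares objective
#' \eqn{\sum_i w_i (d_i - \epsilon(\lambda_i; c))^2} with
#' \eqn{d_i = \hat\delta^{(E)}(\lambda_i) - 1/2} and weights
#' \eqn{w_i = 1/v_i} (inverse sample variances, the maximum-likelihood
#' weighting under the central-limit Gaussian model of the sample means).
#' The problem is non-convex; it is attacked by Levenberg--Marquardt
#' nonlinear least squares from \code{nStarts} initial points drawn
#' uniformly from \eqn{[-h, h]^4}, keeping the lowest-cost solution whose
#' denominator is strictly positive on a dense \eqn{\lambda} grid, and
#' recording all distinct local minima found.
#'
#' The \eqn{\lambda = 0} point is excluded (zero variance; the model
#' already enforces \eqn{\epsilon(0; c) = -1/2} structurally).
#'
#' @param table a [CalibrationTable-class] with at least 5 points at
#'   \eqn{\lambda > 0}.
#' @param nStarts number of random initial points (default 100).
#' @param boxHalfwidth \eqn{h}, half-width of the start box (default 20).
#' @param seed seed for start-point generation.
#' @return A \code{CorrectionFit}: see [fitSummary()]; the fitted
#'   parameters are in slot \code{params}.
#' @export
fitCorrection <- function(table, nStarts = 100L, boxHalfwidth = 20, seed = 1L) {
  stopifnot(is(table, "CalibrationTable"))
  keep <- table@lambdas > 0
  if (sum(keep) < 5) stop("need at least 5 calibration points with lambda > 0", call. = FALSE)
  lambda <- table@lambdas[keep]
  d <- table@means[keep] - 0.5
  sqrtw <- 1 / sqrt(table@variances[keep])
  set.seed(seed)
  starts <- matrix(stats::runif(4 * nStarts, -boxHalfwidth, boxHalfwidth), ncol = 4)
  sols <- vector("list", nStarts)
  costs <- rep(NA_real_, nStarts)
  valid <- logical(nStarts)
  for (s in seq_len(nStarts)) {
    fit <- try(minpack.lm::nls.lm(par = starts[s, ], fn = .fitResiduals,
                                  lambda = lambda, d = d, sqrtw = sqrtw,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 400, ftol = 1e-12, ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    cvec <- unname(fit$par)
    sols[[s]] <- cvec
    costs[s] <- sum(.fitResiduals(cvec, lambda, d, sqrtw)^2)
    valid[s] <- .denomPositive(cvec[2], cvec[3], cvec[4])
  }
  if (!any(valid))
    stop("calibration failure: no start produced a denominator-positive solution",
         call. = FALSE)
  ok <- which(valid)
  best <- ok[which.min(costs[ok])]
  minima <- do.call(rbind, lapply(which(!is.na(costs)), function(s)
    data.frame(c1 = sols[[s]][1], c2 = sols[[s]][2], c3 = sols[[s]][3],
               c4 = sols[[s]][4], cost = costs[s], valid = valid[s])))
  ## collapse numerically identical minima
  key <- apply(round(as.matrix(minima[, 1:4]), 3), 1, paste, collapse = ",")
  minima <- minima[!duplicated(key), , drop = FALSE]
  minima <- minima[order(minima$cost), , drop = FALSE]
  rownames(minima) <- NULL
  params <- fitParams(sols[[best]],
                      provenance = sprintf("fitCorrection: S=%d, nStarts=%d, seed=%d",
                                           table@samples, nStarts, seed))
  new("CorrectionFit", params = params, cost = costs[best], minima = minima,
      nStarts = as.integer(nStarts), seed = as.integer(seed))
}

#' Multistart fit report
#'
#' Result of [fitCorrection()]: the best valid parameter vector, its
#' weighted least-squares cost, and the distinct local minima encountered
#' across restarts.
#'
#' @slot params best-fit [FitParams-class].
#' @slot cost weighted least-squares cost at the optimum.
#' @slot minima data.frame of distinct local minima (c1..c4, cost, valid).
#' @slot nStarts,seed multistart protocol record.
#' @export
setClass("CorrectionFit",
         representation(params = "FitParams", cost = "numeric",
                        minima = "data.frame", nStarts = "integer",
                        seed = "integer"))

setMethod("show", "CorrectionFit", function(object) {
  cat("CorrectionFit: cost =", format(object@cost), "over", object@nStarts,
      "starts (", nrow(object@minima), "distinct minima ), seed =", object@seed, "\n")
  show(object@params)
})

#' @describeIn CorrectionFit-class the local-minima table.
#' @param fit a \code{CorrectionFit}.
#' @export
fitSummary <- function(fit) {
  stopifnot(is(fit, "CorrectionFit"))
  fit@minima
}

#' Signed percentage error of an expected-fidelity approximation
#'
#' \eqn{e(\lambda_i) = 100\,(\delta^{(X)}(\lambda_i) -
#' \hat\delta^{(E)}(\lambda_i)) / \hat\delta^{(E)}(\lambda_i)} for each
#' \eqn{\lambda_i > 0} of the table, where \eqn{\delta^{(X)}} is either a
#' constant (e.g. the classical \eqn{1/2}) or the calibrated
#' \eqn{\delta^{(NE)}(\cdot)} from a [FitParams-class].
#'
#' @param table a [CalibrationTable-class].
#' @param approximation scalar constant, numeric vector parallel to the
#'   table grid, or [FitParams-class].
#' @return data.frame with columns \code{lambda}, \code{error} (percent).
#' @export
percentageErrorCurve <- function(table, approximation) {
  stopifnot(is(table, "CalibrationTable"))
  keep <- table@lambdas > 0 & table@means > 0
  lambda <- table@lambdas[keep]
  mhat <- table@means[keep]
  dx <- if (is(approximation, "FitParams")) deltaNE(lambda, approximation)
        else if (is.numeric(approximation) && length(approximation) == 1)
          rep(approximation, length(lambda))
        else if (is.numeric(approximation) && length(approximation) == length(table@lambdas))
          approximation[keep]
        else stop("approximation must be a scalar, a per-grid-point vector, or FitParams",
                  call. = FALSE)
  data.frame(lambda = lambda, error = 100 * (dx - mhat) / mhat)
}
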
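## Poisson central moments and the truncated series expansion of the
## expected KL fidelity delta^(E)(lambda) = E[F(Y_lambda)].

#' Central moments of a Poisson random variable as exact polynomials
#'
#' Computes the central moment \eqn{\eta_i(Y_\lambda) = E[(Y_\lambda -
#' \lambda)^i]} of a Poisson variable with mean \eqn{\lambda} as an exact
#' polynomial in \eqn{\lambda}, via the classical recursion
#' \deqn{\eta_1 = 0,\quad \eta_2 = \lambda,\quad
#'   \eta_{i+2} = \lambda\left(\frac{d\eta_{i+1}}{d\lambda} + (i+1)\,\eta_i\right),}
#' with the derivative taken symbolically on the coefficient list.
#'
#' @param i moment order, integer \eqn{\ge 1}.
#' @return A [RationalPolynomial-class] with integer coefficients, e.g.
#'   \eqn{\eta_4 = \lambda + 3\lambda^2}.
#' @examples
#' centralMoment(2)   # lambda
#' centralMoment(4)   # lambda + 3*lambda^2
#' @export
centralMoment <- function(i) {
  if (length(i) != 1 || i != round(i) || i < 1)
    stop("moment order i must be a single integer >= 1", call. = FALSE)
  etas <- .centralMomentList(i)
  etas[[i]]
}

## eta_1 .. eta_maxOrder as a list of RationalPolynomial
.centralMomentList <- function(maxOrder) {
  etas <- vector("list", max(maxOrder, 2L))
  etas[[1]] <- rationalPolynomial(0)
  etas[[2]] <- rationalPolynomial(c(0, 1))
  if (maxOrder <= 2) return(etas)
  for (k in 1:(maxOrder - 2)) {
    ## eta_{k+2} = lambda * ( d eta_{k+1} / d lambda + (k+1) * eta_k )
    inner <- .polyAdd(.polyDeriv(etas[[k + 1]]), .polyScale(etas[[k]], k + 1))
    etas[[k + 2]] <- .polyShiftUp(inner)
  }
  etas
}

#' Moment-ratio polynomials P_i
#'
#' The polynomial \eqn{P_i(\lambda) = \eta_{i+2}(Y_\lambda)/\lambda}, which
#' is an ordinary polynomial of degree \eqn{\lfloor i/2 \rfloor} with unit
#' constant term (every Poisson central moment of order \eqn{\ge 2} is
#' divisible by \eqn{\lambda}).  These are the building blocks of the
#' truncated expansion of the expected KL fidelity.
#'
#' @param i index, integer \eqn{\ge 0}; \eqn{P_0 = P_1 = 1},
#'   \eqn{P_2 = 1 + 3\lambda}, \eqn{P_3 = 1 + 10\lambda}, ...
#' @return A [RationalPolynomial-class] with integer coefficients.
#' @export
momentRatioPoly <- function(i) {
  if (length(i) != 1 || i != round(i) || i < 0)
    stop("index i must be a single integer >= 0", call. = FALSE)
  .polyShiftDown(centralMoment(i + 2))
}

#' Truncated series expansion of the expected KL fidelity
#'
#' For a Poisson variable \eqn{Y_\lambda} and the per-pixel KL fidelity
#' \eqn{F(Y_\lambda) = \lambda - Y_\lambda\ln\lambda + Y_\lambda\ln
#' Y_\lambda - Y_\lambda}, truncating the logarithm's Taylor expansion at
#' order \eqn{N} yields
#' \deqn{\delta^{(E)}(\lambda) = E[F(Y_\lambda)]
#'   = \sum_{i=0}^{N-1} \gamma_i^{(N)} \lambda^{-i} + R_N(\lambda).}
#' This function computes the exact rational coefficients
#' \eqn{\gamma_i^{(N)}} by combining the series weights
#' \eqn{\omega_i^{(N)}} with the coefficients of the moment-ratio
#' polynomials \eqn{P_i}.  The weights are
#' \eqn{\omega_i^{(N)} = (-1)^i/((i+1)(i+2))} for \eqn{i \le N-2} and
#' \eqn{(-1)^i/(i+1)} for \eqn{i = N-1}.
#'
#' The expansion is valid only asymptotically: the coefficient sequence
#' grows, so the series diverges for small \eqn{\lambda} (see
#' [convergenceProbability()]), which is precisely why the constant
#' low-order truncation \eqn{1/2} fails in the low-count regime.
#'
#' @param N truncation order, integer \eqn{\ge 1}.
#' @param cap largest supported order (default 12); beyond it, exact
#'   integer coefficients become expensive and are refused explicitly.
#' @return A \code{SeriesExpansion} object; see [seriesGamma()].
#' @examples
#' seriesGamma(seriesCoefficients(3))$value   # 1/2, 5/6, 1/3
#' @export
seriesCoefficients <- function(N, cap = 12L) {
  if (length(N) != 1 || N != round(N) || N < 1)
    stop("truncation order N must be a single integer >= 1", call. = FALSE)
  if (N > cap)
    stop("unsupported truncation order: N = ", N, " exceeds the configured cap ",
         cap, call. = FALSE)
  etas <- .centralMomentList(N + 1L)
  ## omega_i^(N)
  iAll <- 0:(N - 1)
  omegaNum <- (-1)^iAll
  omegaDen <- ifelse(iAll <= N - 2, (iAll + 1) * (iAll + 2), iAll + 1)
  gNum <- rep(0, N); gDen <- rep(1, N)
  for (i in iAll) {
    Pi <- .polyShiftDown(etas[[i + 2]])
    theta <- polyCoefficients(Pi)
    for (r in seq_len(nrow(theta))) {
      k <- i - theta$power[r]          # contributes to lambda^{-k}
      if (k >= 0 && k <= N - 1) {
        term <- .rmul(omegaNum[i + 1], omegaDen[i + 1], theta$num[r], theta$den[r])
        s <- .radd(gNum[k + 1], gDen[k + 1], term$num, term$den)
        gNum[k + 1] <- s$num; gDen[k + 1] <- s$den
      }
    }
  }
  new("SeriesExpansion", order = as.integer(N),
      gammaNum = gNum, gammaDen = gDen,
      omegaNum = omegaNum, omegaDen = omegaDen)
}

#' Truncated series expansion container
#'
#' Holds the exact rational coefficients \eqn{\gamma_i^{(N)}} (powers
#' \eqn{\lambda^{-i}}, \eqn{i = 0,\dots,N-1}) of the order-\eqn{N}
#' truncation of \eqn{E[F(Y_\lambda)]}, together with the series weights
#' \eqn{\omega_i^{(N)}}.
#'
#' @slot order truncation order N.
#' @slot gammaNum,gammaDen exact rational \eqn{\gamma} coefficients.
#' @slot omegaNum,omegaDen exact rational \eqn{\omega} weights.
#' @export
setClass("SeriesExpansion",
         representation(order = "integer",
                        gammaNum = "numeric", gammaDen = "numeric",
                        omegaNum = "numeric", omegaDen = "numeric"))

setValidity("SeriesExpansion", function(object) {
  N <- object@order
  if (length(object@gammaNum) != N || length(object@gammaDen) != N)
    return("gamma must have length equal to the order")
  if (length(object@omegaNum) != N || length(object@omegaDen) != N)
    return("omega must have length equal to the order")
  g0 <- object@gammaNum[1] / object@gammaDen[1]
  if (N == 1 && g0 != 1) return("gamma_0 must be 1 at order 1")
  if (N >= 2 && g0 != 1 / 2) return("gamma_0 must be 1/2 at orders >= 2")
  TRUE
})

#' @describeIn seriesCoefficients extract the gamma coefficients as a
#'   data.frame with columns \code{i}, \code{num}, \code{den},
#'   \code{value}.
#' @param expansion a \code{SeriesExpansion}.
#' @export
seriesGamma <- function(expansion) {
  stopifnot(is(expansion, "SeriesExpansion"))
  data.frame(i = 0:(expansion@order - 1),
             num = expansion@gammaNum, den = expansion@gammaDen,
             value = expansion@gammaNum / expansion@gammaDen)
}

#' @describeIn seriesCoefficients extract the omega weights analogously.
#' @export
seriesOmega <- function(expansion) {
  stopifnot(is(expansion, "SeriesExpansion"))
  data.frame(i = 0:(expansion@order - 1),
             num = expansion@omegaNum, den = expansion@omegaDen,
             value = expansion@omegaNum / expansion@omegaDen)
}

setMethod("show", "SeriesExpansion", function(object) {
  g <- seriesGamma(object)
  cat("SeriesExpansion of order", object@order, "\n")
  cat("  delta^(E)(lambda) ~", paste0(.fracString(g$num, g$den),
      ifelse(g$i == 0, "", paste0("/lambda^", g$i)), collapse = " + "),
      "+ remainder\n")
})

#' Evaluate the truncated expected-fidelity series
#'
#' Returns \eqn{\sum_{i=0}^{N-1} \gamma_i^{(N)} \lambda^{-i}} in floating
#' point.  Accurate only for large \eqn{\lambda}; diverges with \eqn{N}
#' for \eqn{\lambda \lesssim 1}.
#'
#' @param lambda positive Poisson mean(s).
#' @param N truncation order.
#' @param cap passed to [seriesCoefficients()].
#' @return Numeric vector of the same length as \code{lambda}.
#' @export
truncatedExpectedValue <- function(lambda, N, cap = 12L) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  g <- seriesGamma(seriesCoefficients(N, cap = cap))
  vapply(lambda, function(l) sum(g$value * l^(-g$i)), numeric(1))
}

#' Series-convergence diagnostic
#'
#' The logarithm expansion underlying the truncated series converges (for
#' \eqn{N \to \infty}) only on the event \eqn{0 < Y_\lambda \le 2\lambda};
#' this returns \eqn{P(0 < Y_\lambda \le 2\lambda) =
#' \sum_{i=1}^{\lfloor 2\lambda \rfloor} P(Y_\lambda = i)}, which tends to
#' 1 as \eqn{\lambda \to +\infty} but is far below 1 in the low-count
#' regime, where the series expansion therefore cannot represent
#' \eqn{E[F(Y_\lambda)]}.
#'
#' @param lambda positive Poisson mean(s).
#' @return Probabilities in \eqn{[0, 1]}.
#' @export
convergenceProbability <- function(lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  k <- floor(2 * lambda)
  out <- numeric(length(lambda))
  pos <- k >= 1
  out[pos] <- stats::ppois(k[pos], lambda[pos]) - stats::dpois(0, lambda[pos])
  out
}
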
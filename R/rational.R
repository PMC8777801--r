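## Exact rational arithmetic on double-backed integers.
##
## The series analysis of the expected KL fidelity requires exact rational
## coefficients: sign patterns and magnitudes of the gamma_i^(N) drive the
## divergence argument, and floating-point accumulation would blur them.
## Rationals are stored as reduced numerator/denominator pairs of
## integer-valued doubles; every product and sum is guarded against leaving
## the exactly-representable integer range (|x| <= 2^53).

.INT_EXACT_MAX <- 2^53

.checkExact <- function(x) {
  if (any(abs(x) > .INT_EXACT_MAX))
    stop("exact integer overflow: coefficient exceeds 2^53; ",
         "reduce the truncation order", call. = FALSE)
  x
}

.rgcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(act <- b > 0)) {
    r <- a[act] %% b[act]
    a[act] <- b[act]
    b[act] <- r
  }
  pmax(a, 1)
}

## reduce num/den vectors to lowest terms with positive denominators
.rreduce <- function(num, den) {
  if (any(den == 0)) stop("zero denominator in rational", call. = FALSE)
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- .rgcd(num, den)
  list(num = num / g, den = den / g)
}

.radd <- function(n1, d1, n2, d2) {
  g <- .rgcd(d1, d2)
  d1r <- d1 / g
  num <- .checkExact(.checkExact(n1 * (d2 / g)) + .checkExact(n2 * d1r))
  den <- .checkExact(d1r * d2)
  .rreduce(num, den)
}

.rmul <- function(n1, d1, n2, d2) {
  ## cross-reduce before multiplying to keep magnitudes small
  g1 <- .rgcd(n1, d2)
  g2 <- .rgcd(n2, d1)
  num <- .checkExact((n1 / g1) * (n2 / g2))
  den <- .checkExact((d1 / g2) * (d2 / g1))
  .rreduce(num, den)
}

#' Exact-coefficient polynomial in the Poisson mean
#'
#' A polynomial \eqn{p(\lambda) = \sum_j (num_j/den_j) \lambda^j} whose
#' coefficients are exact rational numbers, stored as reduced
#' numerator/denominator pairs of integer-valued doubles.  Used as the
#' backbone of the Poisson central-moment recursion and the truncated
#' series expansion of the expected Kullback--Leibler fidelity.
#'
#' @slot num numeric vector of integer-valued numerators; element \code{j}
#'   is the coefficient of \eqn{\lambda^{j-1}}.
#' @slot den numeric vector of integer-valued positive denominators,
#'   parallel to \code{num}; each pair is in lowest terms.
#' @seealso [rationalPolynomial()], [centralMoment()], [momentRatioPoly()]
#' @export
setClass("RationalPolynomial",
         representation(num = "numeric", den = "numeric"))

setValidity("RationalPolynomial", function(object) {
  n <- object@num; d <- object@den
  if (length(n) != length(d)) return("num and den must have equal length")
  if (length(n) == 0) return("empty coefficient vector")
  if (any(n != round(n)) || any(d != round(d))) return("coefficients must be integer-valued")
  if (any(d < 1)) return("denominators must be positive")
  if (any(.rgcd(n, d) != 1 & n != 0)) return("coefficients must be in lowest terms")
  if (length(n) > 1 && n[length(n)] == 0) return("trailing zero coefficient: degree must match storage")
  TRUE
})

#' Construct an exact rational polynomial
#'
#' @param num integer-valued numerators, coefficient of \eqn{\lambda^{j}}
#'   at position \code{j + 1}.
#' @param den integer-valued denominators (recycled if scalar).
#' @return A [RationalPolynomial-class] object, reduced to lowest terms
#'   with trailing zeros stripped.
#' @examples
#' rationalPolynomial(c(0, 1, 3))      # lambda + 3 lambda^2
#' rationalPolynomial(c(1, 5, 2), c(2, 6, 6))
#' @export
rationalPolynomial <- function(num, den = 1) {
  if (length(den) == 1) den <- rep(den, length(num))
  r <- .rreduce(.checkExact(num), .checkExact(den))
  num <- r$num; den <- r$den
  deg <- max(c(0, which(num != 0) - 1))
  new("RationalPolynomial", num = num[seq_len(deg + 1)], den = den[seq_len(deg + 1)])
}

#' @describeIn rationalPolynomial polynomial degree (index of last nonzero
#'   coefficient; 0 for the zero polynomial).
#' @param p a \code{RationalPolynomial}.
#' @export
polyDegree <- function(p) length(p@num) - 1L

#' Coefficients of a rational polynomial
#'
#' @param p a [RationalPolynomial-class].
#' @return A data.frame with columns \code{power}, \code{num}, \code{den},
#'   \code{value} (floating-point quotient).
#' @export
polyCoefficients <- function(p) {
  stopifnot(is(p, "RationalPolynomial"))
  data.frame(power = seq_along(p@num) - 1L, num = p@num, den = p@den,
             value = p@num / p@den)
}

## p + q, exact
.polyAdd <- function(p, q) {
  n <- max(length(p@num), length(q@num))
  pad <- function(x, fill) c(x, rep(fill, n - length(x)))
  r <- .radd(pad(p@num, 0), pad(p@den, 1), pad(q@num, 0), pad(q@den, 1))
  rationalPolynomial(r$num, r$den)
}

## scalar rational (a/b) * p, exact
.polyScale <- function(p, a, b = 1) {
  r <- .rmul(p@num, p@den, rep(a, length(p@num)), rep(b, length(p@num)))
  rationalPolynomial(r$num, r$den)
}

## multiply by lambda: shift coefficients up one power
.polyShiftUp <- function(p) rationalPolynomial(c(0, p@num), c(1, p@den))

## d p / d lambda, symbolic on the coefficient list
.polyDeriv <- function(p) {
  if (length(p@num) == 1) return(rationalPolynomial(0))
  j <- seq_len(length(p@num) - 1)
  r <- .rmul(p@num[-1], p@den[-1], j, rep(1, length(j)))
  rationalPolynomial(r$num, r$den)
}

## divide by lambda; requires zero constant term
.polyShiftDown <- function(p) {
  if (p@num[1] != 0) stop("polynomial has nonzero constant term; not divisible by lambda",
                          call. = FALSE)
  if (length(p@num) == 1) return(rationalPolynomial(0))
  rationalPolynomial(p@num[-1], p@den[-1])
}

#' Evaluate a rational polynomial in floating point
#'
#' @param p a [RationalPolynomial-class].
#' @param lambda numeric vector of evaluation points.
#' @return Numeric vector \eqn{p(\lambda)} (Horner evaluation of the
#'   floating-point quotients).
#' @export
evalPoly <- function(p, lambda) {
  co <- p@num / p@den
  out <- rep(co[length(co)], length(lambda))
  for (j in rev(seq_len(length(co) - 1))) out <- out * lambda + co[j]
  out
}

.fracString <- function(num, den) {
  ifelse(den == 1, as.character(num), paste0(num, "/", den))
}

setMethod("show", "RationalPolynomial", function(object) {
  co <- .fracString(object@num, object@den)
  pow <- seq_along(object@num) - 1L
  keep <- object@num != 0 | pow == 0
  terms <- paste0("(", co[keep], ")",
                  ifelse(pow[keep] == 0, "", paste0("*lambda^", pow[keep])))
  cat("RationalPolynomial of degree", polyDegree(object), "\n ",
      paste(terms, collapse = " + "), "\n")
})
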
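## KL fidelity, the rational correction model, and the discrepancy values
## used by the theoretical / approximate / nearly exact principles.

#' Per-pixel generalized Kullback--Leibler fidelity
#'
#' \eqn{F(\lambda; y) = \lambda - y\ln\lambda + y\ln y - y}, with the
#' convention \eqn{y \ln y = 0} at \eqn{y = 0}.  \eqn{F \ge 0} with
#' equality iff \eqn{\lambda = y}; for \eqn{y > 0} and \eqn{\lambda = 0}
#' the value is \code{Inf} (returned, not an error, so that root finding
#' over the regularization parameter can bracket safely).
#'
#' @param lambda non-negative expected counts (vectorized).
#' @param y non-negative observed counts (vectorized, recycled).
#' @return Non-negative numeric vector.
#' @examples
#' klTerm(7, 7)      # 0
#' klTerm(3, 0)      # 3
#' klTerm(1, 2)      # 2*log(2) - 1
#' @export
klTerm <- function(lambda, y) {
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  if (any(y < 0)) stop("y must be non-negative", call. = FALSE)
  n <- max(length(lambda), length(y))
  lambda <- rep_len(lambda, n); y <- rep_len(y, n)
  out <- lambda - y
  pos <- y > 0
  if (any(pos)) {
    yl <- y[pos]
    out[pos] <- out[pos] - yl * log(lambda[pos]) + yl * log(yl)
  }
  ## lambda == y == 0 gives 0 - 0 = 0; lambda == 0, y > 0 gives +Inf via -y*log(0)
  out
}

#' Generalized KL divergence between expected and observed counts
#'
#' @param lambda non-negative vector of expected counts.
#' @param y count vector of the same length.
#' @return \eqn{\sum_i F(\lambda_i; y_i)}.
#' @export
klDivergence <- function(lambda, y) {
  if (length(lambda) != length(y))
    stop("lambda and y must have the same length", call. = FALSE)
  sum(klTerm(lambda, y))
}

#' Fitted parameters of the rational correction model
#'
#' The correction \eqn{\epsilon(\lambda; c)} to the constant approximation
#' \eqn{1/2} of the expected KL fidelity is modelled as the rational
#' function
#' \deqn{\epsilon(\lambda; c) = \frac{\lambda^2 + c_1\lambda + c_2}
#'   {12\lambda^3 + c_3\lambda^2 + c_4\lambda - 2c_2},}
#' which enforces \eqn{\epsilon(0; c) = -1/2} (so the corrected expected
#' value vanishes at \eqn{\lambda = 0}) and \eqn{\epsilon(\lambda; c) \sim
#' 1/(12\lambda)} as \eqn{\lambda \to +\infty} (the leading series term).
#'
#' Validity requires the denominator to be strictly positive on a dense
#' grid over \eqn{[0, \lambda_{max}]} (default \eqn{10^4}), so the
#' correction is continuous on the whole operating range.
#'
#' @slot c1,c2,c3,c4 model parameters.
#' @slot provenance free-text description of how the parameters were
#'   obtained (calibration size, seed, ...).
#' @seealso [fitParams()], [referenceFitParams()], [epsilonCorrection()]
#' @export
setClass("FitParams",
         representation(c1 = "numeric", c2 = "numeric", c3 = "numeric",
                        c4 = "numeric", provenance = "character"))

.denomPositive <- function(c2, c3, c4, lambdaMax = 1e4) {
  grid <- c(seq(0, 10, by = 0.005), exp(seq(log(10), log(lambdaMax), length.out = 4000)))
  den <- 12 * grid^3 + c3 * grid^2 + c4 * grid - 2 * c2
  all(den > 0)
}

setValidity("FitParams", function(object) {
  for (s in c("c1", "c2", "c3", "c4"))
    if (length(slot(object, s)) != 1 || !is.finite(slot(object, s)))
      return(paste0(s, " must be a finite scalar"))
  if (!.denomPositive(object@c2, object@c3, object@c4))
    return("denominator 12*l^3 + c3*l^2 + c4*l - 2*c2 must be strictly positive on [0, 1e4]")
  TRUE
})

#' @describeIn FitParams-class constructor.
#' @param c1,c2,c3,c4 model parameters (or \code{c1} a length-4 vector).
#' @param provenance description string.
#' @export
fitParams <- function(c1, c2 = NULL, c3 = NULL, c4 = NULL,
                      provenance = "user-supplied") {
  if (length(c1) == 4 && is.null(c2)) {
    c2 <- c1[2]; c3 <- c1[3]; c4 <- c1[4]; c1 <- c1[1]
  }
  new("FitParams", c1 = as.numeric(c1), c2 = as.numeric(c2),
      c3 = as.numeric(c3), c4 = as.numeric(c4), provenance = provenance)
}

#' Reference correction parameters
#'
#' The frozen reference parameter vector \eqn{\hat c = (+2.5792, -1.5205,
#' -5.6244, +17.9347)} of the rational correction model, obtained from a
#' large-scale Monte Carlo calibration (\eqn{5\times 10^7} samples per
#' grid point on the standard three-part \eqn{\lambda} grid, multistart
#' weighted least squares).  Recalibrations with [fitCorrection()] produce
#' separate [FitParams-class] objects and never overwrite this constant.
#'
#' @return A [FitParams-class] object.
#' @export
referenceFitParams <- function() {
  fitParams(2.5792, -1.5205, -5.6244, 17.9347,
            provenance = "reference calibration (S = 5e7, multistart weighted LS)")
}

#' @describeIn FitParams-class parameters as a named numeric vector.
#' @param object,params a \code{FitParams}.
#' @export
fitCoef <- function(params) {
  stopifnot(is(params, "FitParams"))
  c(c1 = params@c1, c2 = params@c2, c3 = params@c3, c4 = params@c4)
}

setMethod("show", "FitParams", function(object) {
  cat("FitParams: c = (", paste(sprintf("%+.4f", fitCoef(object)), collapse = ", "),
      ")\n  provenance:", object@provenance, "\n")
})

#' Serialize / deserialize correction parameters as JSON
#'
#' @param params a [FitParams-class].
#' @param path file path of the JSON document.
#' @return \code{writeFitParams} returns \code{path} invisibly;
#'   \code{readFitParams} returns a [FitParams-class].
#' @export
writeFitParams <- function(params, path) {
  stopifnot(is(params, "FitParams"))
  jsonlite::write_json(c(as.list(fitCoef(params)),
                         list(provenance = params@provenance)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFitParams
#' @export
readFitParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fitParams(x$c1, x$c2, x$c3, x$c4,
            provenance = if (is.null(x$provenance)) "json" else x$provenance)
}

#' Rational correction to the constant expected-fidelity approximation
#'
#' Evaluates \eqn{\epsilon(\lambda; c)}; see [FitParams-class] for the
#' functional form.  \eqn{\epsilon(0; c) = -1/2} exactly and
#' \eqn{\lambda\,\epsilon(\lambda; c) \to 1/12} as \eqn{\lambda \to
#' +\infty} for any valid parameters.
#'
#' @param lambda non-negative numeric vector.
#' @param params a [FitParams-class]; defaults to [referenceFitParams()].
#' @return Numeric vector \eqn{\epsilon(\lambda; c)}.
#' @export
epsilonCorrection <- function(lambda, params = referenceFitParams()) {
  stopifnot(is(params, "FitParams"))
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  den <- 12 * lambda^3 + params@c3 * lambda^2 + params@c4 * lambda - 2 * params@c2
  if (any(den <= 0))
    stop("correction denominator non-positive at some lambda", call. = FALSE)
  (lambda^2 + params@c1 * lambda + params@c2) / den
}

#' Nearly exact per-pixel expected fidelity
#'
#' \eqn{\delta^{(NE)}(\lambda) = 1/2 + \epsilon(\lambda; c)}: the
#' calibrated approximation of \eqn{E[F(Y_\lambda)]}, satisfying
#' \eqn{\delta^{(NE)}(0) = 0} and \eqn{\delta^{(NE)}(\lambda) \to 1/2}.
#'
#' @inheritParams epsilonCorrection
#' @export
deltaNE <- function(lambda, params = referenceFitParams()) {
  0.5 + epsilonCorrection(lambda, params)
}

#' Discrepancy-value specification
#'
#' Selects which discrepancy principle sets the target value \eqn{\Delta}:
#' \describe{
#'   \item{theoretical}{oracle value \eqn{\Delta^{(T)} = \sum_i
#'     F(\bar\lambda_i; y_i)} computed from the known noiseless expected
#'     counts \eqn{\bar\lambda = H\bar x + b} (requires
#'     \code{referenceLambda}).}
#'   \item{approximate}{classical constant \eqn{\Delta^{(A)} = m/2}.}
#'   \item{nearly_exact}{\eqn{\Delta^{(NE)} = m/2 + \sum_i
#'     \epsilon(\hat\lambda_i; c)} — a function of the current restored
#'     expected counts (requires \code{params}).}
#' }
#'
#' @slot variant one of \code{"theoretical"}, \code{"approximate"},
#'   \code{"nearly_exact"}.
#' @slot referenceLambda noiseless expected counts (theoretical variant).
#' @slot params [FitParams-class] (nearly exact variant).
#' @export
setClass("DeltaSpec",
         representation(variant = "character", referenceLambda = "numeric",
                        params = "ANY"),
         prototype(referenceLambda = numeric(0), params = NULL))

setValidity("DeltaSpec", function(object) {
  if (!object@variant %in% c("theoretical", "approximate", "nearly_exact"))
    return("variant must be one of theoretical / approximate / nearly_exact")
  if (object@variant == "theoretical") {
    if (length(object@referenceLambda) == 0)
      return("theoretical variant requires referenceLambda = H %*% xbar + b")
    if (any(object@referenceLambda < 0))
      return("referenceLambda must be non-negative")
  }
  if (object@variant == "nearly_exact" && !is(object@params, "FitParams"))
    return("nearly_exact variant requires FitParams")
  TRUE
})

#' @describeIn DeltaSpec-class constructor.
#' @param variant discrepancy-principle variant.
#' @param referenceLambda noiseless expected counts (theoretical only).
#' @param params correction parameters (nearly exact only; defaults to
#'   [referenceFitParams()]).
#' @export
deltaSpec <- function(variant = c("nearly_exact", "approximate", "theoretical"),
                      referenceLambda = NULL, params = NULL) {
  variant <- match.arg(variant)
  if (variant == "nearly_exact" && is.null(params)) params <- referenceFitParams()
  new("DeltaSpec", variant = variant,
      referenceLambda = if (is.null(referenceLambda)) numeric(0) else as.numeric(referenceLambda),
      params = params)
}

setMethod("show", "DeltaSpec", function(object) {
  cat("DeltaSpec:", object@variant, "discrepancy principle\n")
})

#' Discrepancy value for a given principle
#'
#' Evaluates the target value \eqn{\Delta} of the discrepancy equation for
#' the chosen variant; see [DeltaSpec-class].  \code{lambdaHat} is the
#' current vector of restored expected counts (used by the nearly exact
#' variant only); \code{y} the observed counts (used by the theoretical
#' variant only).
#'
#' @param spec a [DeltaSpec-class].
#' @param lambdaHat non-negative vector, length \eqn{m}.
#' @param y count vector, length \eqn{m}.
#' @return A non-negative scalar.
#' @export
deltaValue <- function(spec, lambdaHat, y) {
  stopifnot(is(spec, "DeltaSpec"))
  if (length(lambdaHat) != length(y))
    stop("lambdaHat and y must have the same length", call. = FALSE)
  m <- length(y)
  switch(spec@variant,
    theoretical = {
      if (length(spec@referenceLambda) != m)
        stop("referenceLambda length does not match y", call. = FALSE)
      klDivergence(spec@referenceLambda, y)
    },
    approximate = m / 2,
    nearly_exact = m / 2 + sum(epsilonCorrection(lambdaHat, spec@params)))
}
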
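## ADMM solver for the TV-KL restoration model with per-iteration
## discrepancy-principle selection of the regularization parameter.
##
## The model is  min_{x >= 0}  TV(x) + mu * KL(Hx + b; y).  Splitting
## variables lambda = Hx + b (fidelity), g = Dx (TV), z = x (positivity)
## gives four closed-form subproblems per sweep; the effective parameter
## gamma = mu / beta_lambda is re-selected at every iteration as the root
## of the discrepancy equation D(gamma) = Delta(gamma).

#' Solver configuration for the DP-ADMM scheme
#'
#' @slot dpVariant a [DeltaSpec-class] choosing the discrepancy principle
#'   (or the string-constructed default, nearly exact).
#' @slot betaLambda,betaG,betaZ positive ADMM penalty parameters; values
#'   in \eqn{[0.5, 2]} work well in practice.
#' @slot tol relative-change stopping tolerance on \eqn{x} (default
#'   \eqn{10^{-5}}).
#' @slot maxIter iteration cap.
#' @slot rootSolver \code{"bisection"} (default, robust) or
#'   \code{"secant"} (safeguarded, falls back to bisection steps).
#' @slot rootTol discrepancy-equation tolerance per pixel: the accepted
#'   root satisfies \eqn{|D(\gamma) - \Delta(\gamma)| \le rootTol \cdot m}.
#' @slot gammaInit initial bracketing guess for \eqn{\gamma}.
#' @slot seed integer recorded for provenance.
#' @export
setClass("SolverConfig",
         representation(dpVariant = "DeltaSpec",
                        betaLambda = "numeric", betaG = "numeric", betaZ = "numeric",
                        tol = "numeric", maxIter = "integer",
                        rootSolver = "character", rootTol = "numeric",
                        gammaInit = "numeric", seed = "integer"))

setValidity("SolverConfig", function(object) {
  if (any(c(object@betaLambda, object@betaG, object@betaZ) <= 0))
    return("penalty parameters must be positive")
  if (object@tol <= 0) return("tol must be positive")
  if (object@maxIter < 1) return("maxIter must be >= 1")
  if (!object@rootSolver %in% c("bisection", "secant"))
    return("rootSolver must be bisection or secant")
  if (object@rootTol <= 0) return("rootTol must be positive")
  if (object@gammaInit <= 0) return("gammaInit must be positive")
  TRUE
})

#' @describeIn SolverConfig-class constructor.
#' @param dpVariant [DeltaSpec-class] or variant name passed to
#'   [deltaSpec()].
#' @param betaLambda,betaG,betaZ ADMM penalty parameters.
#' @param tol stopping tolerance.
#' @param maxIter iteration cap.
#' @param rootSolver root-finding method for the discrepancy equation.
#' @param rootTol per-pixel discrepancy-equation tolerance.
#' @param gammaInit initial \eqn{\gamma} guess.
#' @param seed provenance seed.
#' @export
solverConfig <- function(dpVariant = "nearly_exact",
                         betaLambda = 1, betaG = 1, betaZ = 1,
                         tol = 1e-5, maxIter = 500L,
                         rootSolver = c("bisection", "secant"),
                         rootTol = 1e-6, gammaInit = 1, seed = 1L) {
  if (is.character(dpVariant)) dpVariant <- deltaSpec(dpVariant)
  new("SolverConfig", dpVariant = dpVariant,
      betaLambda = betaLambda, betaG = betaG, betaZ = betaZ,
      tol = tol, maxIter = as.integer(maxIter),
      rootSolver = match.arg(rootSolver), rootTol = rootTol,
      gammaInit = gammaInit, seed = as.integer(seed))
}

setMethod("show", "SolverConfig", function(object) {
  cat("SolverConfig:", object@dpVariant@variant, "DP, beta = (",
      object@betaLambda, object@betaG, object@betaZ, "), tol =", object@tol,
      ", maxIter =", object@maxIter, "\n")
})

#' Group soft-threshold update of the gradient splitting variable
#'
#' Per-pixel isotropic shrinkage: each 2-vector \eqn{w_i} is scaled by
#' \eqn{\max(1 - 1/(\beta_g \|w_i\|_2),\, 0)} — the closed-form minimizer
#' of \eqn{\|g_i\|_2 + (\beta_g/2)\|g_i - w_i\|_2^2}.
#'
#' @param w 2-vector field: \code{list(h =, v =)} of equally sized
#'   matrices.
#' @param betaG positive penalty parameter (threshold \eqn{1/\beta_g}).
#' @return 2-vector field of the same shape.
#' @export
gUpdate <- function(w, betaG) {
  nrm <- sqrt(w$h^2 + w$v^2)
  scale <- pmax(1 - 1 / (betaG * nrm), 0)
  scale[nrm == 0] <- 0
  list(h = w$h * scale, v = w$v * scale)
}

#' Projection onto the non-negative orthant
#'
#' @param q numeric vector or matrix.
#' @return Elementwise \eqn{\max(q, 0)} — the closest non-negative point
#'   in Euclidean norm.
#' @export
zUpdate <- function(q) pmax(q, 0)

#' FFT-domain solve of the ADMM x-subproblem
#'
#' Solves the symmetric positive definite system
#' \deqn{\left(D^T D + \tfrac{\beta_\lambda}{\beta_g} H^T H +
#'   \tfrac{\beta_z}{\beta_g} I\right) x =
#'   D^T\!\left(g - \tfrac{\rho_g}{\beta_g}\right) +
#'   \tfrac{\beta_\lambda}{\beta_g} H^T\!\left(\lambda - b -
#'   \tfrac{\rho_\lambda}{\beta_\lambda}\right) +
#'   \tfrac{\beta_z}{\beta_g}\left(z - \tfrac{\rho_z}{\beta_z}\right)}
#' exactly in the Fourier domain (all operators are block circulant under
#' periodic boundary conditions): one forward and one inverse 2-D FFT.
#'
#' @param model a [DegradationModel-class].
#' @param lambda,g,z current splitting variables (\code{g} a 2-vector
#'   field list).
#' @param rhoLambda,rhoG,rhoZ current multipliers (\code{rhoG} a list).
#' @param betaLambda,betaG,betaZ penalty parameters.
#' @return Updated image matrix \eqn{x}.
#' @export
xUpdate <- function(model, lambda, g, z, rhoLambda, rhoG, rhoZ,
                    betaLambda, betaG, betaZ) {
  rl <- betaLambda / betaG
  rz <- betaZ / betaG
  rhs <- .gradAdjoint(list(h = g$h - rhoG$h / betaG, v = g$v - rhoG$v / betaG)) +
    rl * applyBlur(model, lambda - model@background - rhoLambda / betaLambda,
                   adjoint = TRUE) +
    rz * (z - rhoZ / betaZ)
  eig <- .eigDtD(model@dim) + rl * Mod(model@otf)^2 + rz
  Re(stats::fft(stats::fft(rhs) / eig, inverse = TRUE)) / length(rhs)
}

#' Closed-form solution of the per-pixel fidelity subproblem
#'
#' The unique minimizer over \eqn{\lambda_i > 0} of
#' \eqn{\gamma(\lambda_i - y_i \ln\lambda_i) + \tfrac12(\lambda_i -
#' v_i)^2}:
#' \deqn{\lambda_i(\gamma) = \tfrac12\left(v_i - \gamma +
#'   \sqrt{(v_i - \gamma)^2 + 4 y_i \gamma}\right).}
#' Satisfies \eqn{\lambda_i(0) = \max(v_i, 0)} and \eqn{\lambda_i(\gamma)
#' \to y_i} as \eqn{\gamma \to +\infty}.
#'
#' @param gamma non-negative scalar, the effective regularization
#'   parameter \eqn{\mu/\beta_\lambda}.
#' @param v real vector (blurred iterate plus scaled multiplier).
#' @param y count vector.
#' @return Non-negative vector of the same length as \code{v}.
#' @export
lambdaClosedForm <- function(gamma, v, y) {
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  0.5 * ((v - gamma) + sqrt((v - gamma)^2 + 4 * y * gamma))
}

## KL discrepancy function D(gamma); lambda clamped away from 0 before
## logarithms (transient zeros with y_i > 0 would give +Inf)
.discrepancyD <- function(gamma, v, y) {
  sum(klTerm(pmax(lambdaClosedForm(gamma, v, y), 1e-12), y))
}

.discrepancyDelta <- function(gamma, v, y, spec) {
  if (spec@variant == "nearly_exact")
    deltaValue(spec, pmax(lambdaClosedForm(gamma, v, y), 0), y)
  else deltaValue(spec, v, y)   # constant in gamma
}

#' Root-existence check for the nearly exact discrepancy equation
#'
#' Sufficient condition for the nearly exact discrepancy equation to have
#' a root in \eqn{\gamma}: with \eqn{t = \max(v, 0)} (the fidelity
#' subproblem solution at \eqn{\gamma = 0}), require some \eqn{y_i \ne 0}
#' and
#' \deqn{\sum_i \left[F(t_i; y_i) - \epsilon(t_i; c)\right] \ge m/2.}
#' When it holds, the residual \eqn{G(\gamma) = D(\gamma) -
#' \Delta^{(NE)}(\gamma)} is continuous with \eqn{G(0) \ge 0} and
#' \eqn{G(+\infty) < 0}, so a sign change exists.
#'
#' @param v real vector.
#' @param y count vector of the same length.
#' @param params a [FitParams-class].
#' @return \code{list(ok = logical, statistic = sum, threshold = m/2)}.
#' @export
neRootExists <- function(v, y, params = referenceFitParams()) {
  if (length(v) != length(y)) stop("v and y must have the same length", call. = FALSE)
  t <- pmax(v, 0)
  stat <- sum(klTerm(t, y) - epsilonCorrection(t, params))
  list(ok = any(y != 0) && stat >= length(y) / 2,
       statistic = stat, threshold = length(y) / 2)
}

#' Solve the discrepancy equation for the effective parameter
#'
#' Finds \eqn{\gamma^* \ge 0} with \eqn{|D(\gamma^*) - \Delta(\gamma^*)|
#' \le rootTol \cdot m}, where \eqn{D(\gamma) = \sum_i
#' F(\lambda_i(\gamma); y_i)} is evaluated through the closed-form
#' fidelity update [lambdaClosedForm()].  The bracket \eqn{[0,
#' \gamma_{hi}]} is grown geometrically (factor 10, cap \eqn{10^{12}})
#' until the residual changes sign, then refined by bisection or a
#' safeguarded secant method.
#'
#' Boundary conventions: for the approximate/theoretical variants, if the
#' residual at \eqn{\gamma = 0} is already \eqn{\le 0} (the data term at
#' the unconstrained point is below the target), \eqn{\gamma = 0} is
#' returned.  For the nearly exact variant, if the [neRootExists()]
#' condition fails, \code{NA} is returned and the caller keeps the
#' previous parameter value.
#'
#' @param v real vector (see [lambdaClosedForm()]).
#' @param y count vector.
#' @param spec a [DeltaSpec-class].
#' @param rootTol per-pixel tolerance.
#' @param warmStart initial upper bracket guess (e.g. the previous
#'   iteration's \eqn{\gamma}).
#' @param rootSolver \code{"bisection"} or \code{"secant"}.
#' @return \eqn{\gamma^*}, or \code{NA_real_} when the nearly exact
#'   existence condition fails.
#' @export
discrepancyRoot <- function(v, y, spec, rootTol = 1e-6, warmStart = 1,
                            rootSolver = c("bisection", "secant")) {
  rootSolver <- match.arg(rootSolver)
  stopifnot(is(spec, "DeltaSpec"))
  m <- length(y)
  G <- function(gamma) .discrepancyD(gamma, v, y) -
    .discrepancyDelta(gamma, v, y, spec)
  g0 <- G(0)
  if (spec@variant == "nearly_exact") {
    if (!neRootExists(v, y, spec@params)$ok) return(NA_real_)
  } else if (g0 <= 0) {
    return(0)
  }
  if (g0 <= rootTol * m) return(0)
  hi <- max(warmStart, 1e-6)
  ghi <- G(hi)
  while (ghi > 0 && hi < 1e12) {
    hi <- hi * 10
    ghi <- G(hi)
  }
  if (ghi > 0)
    stop("discrepancy root not found: no sign change up to gamma = 1e12",
         call. = FALSE)
  lo <- 0; glo <- g0
  for (it in seq_len(200)) {
    mid <- if (rootSolver == "secant" && is.finite(glo) && glo != ghi) {
      cand <- lo - glo * (hi - lo) / (ghi - glo)
      if (cand <= lo || cand >= hi) (lo + hi) / 2 else cand
    } else (lo + hi) / 2
    gm <- G(mid)
    if (abs(gm) <= rootTol * m) return(mid)
    if (gm > 0) { lo <- mid; glo <- gm } else { hi <- mid; ghi <- gm }
    if ((hi - lo) <= 1e-12 * max(1, hi)) break
  }
  (lo + hi) / 2
}

#' Restoration result of the DP-ADMM solver
#'
#' @slot x restored image (non-negative, via the positivity splitting
#'   variable at convergence).
#' @slot muHat selected regularization parameter \eqn{\hat\mu =
#'   \gamma^{final} \beta_\lambda}.
#' @slot gamma final effective parameter.
#' @slot trace per-iteration diagnostics: \code{iter}, \code{gamma},
#'   \code{mu}, \code{discrepancy} (D), \code{delta} (target),
#'   \code{epsX}, \code{frozen} (nearly exact update skipped).
#' @slot iterations,converged run summary.
#' @slot residuals named final primal-feasibility residuals (Euclidean
#'   norms of \eqn{\lambda - (Hx+b)}, \eqn{g - Dx}, \eqn{z - x}).
#' @slot config,model inputs for replay.
#' @export
setClass("RestorationResult",
         representation(x = "matrix", muHat = "numeric", gamma = "numeric",
                        trace = "data.frame", iterations = "integer",
                        converged = "logical", residuals = "numeric",
                        config = "SolverConfig",
                        model = "DegradationModel"))

setMethod("show", "RestorationResult", function(object) {
  cat("RestorationResult:", paste(dim(object@x), collapse = "x"),
      "image,", object@config@dpVariant@variant, "DP\n  mu_hat =",
      format(object@muHat), ", iterations =", object@iterations,
      if (object@converged) "(converged)" else "(max iterations)", "\n")
})

#' @describeIn RestorationResult-class the restored image matrix.
#' @param result a \code{RestorationResult}.
#' @export
restoredImage <- function(result) { stopifnot(is(result, "RestorationResult")); result@x }

#' @describeIn RestorationResult-class the per-iteration trace.
#' @export
solverTrace <- function(result) { stopifnot(is(result, "RestorationResult")); result@trace }

#' @describeIn RestorationResult-class the selected regularization
#'   parameter.
#' @export
muHat <- function(result) { stopifnot(is(result, "RestorationResult")); result@muHat }

#' DP-ADMM restoration of a Poisson count image
#'
#' Runs the ADMM on the TV-KL model with automatic per-iteration
#' selection of the regularization parameter by the configured
#' discrepancy principle.  Each sweep: (1) \eqn{v = Hx + b +
#' \rho_\lambda/\beta_\lambda}; (2) \eqn{\gamma} from the discrepancy
#' equation ([discrepancyRoot()], warm-started at the previous value;
#' when the nearly exact existence condition fails the parameter is
#' frozen at its previous value); (3) closed-form \eqn{\lambda}, shrinkage
#' \eqn{g}, projection \eqn{z}, FFT solve \eqn{x}; (4) dual ascent on the
#' three multipliers.  Stops when the relative change of \eqn{x} falls
#' below \code{tol} or at \code{maxIter}.
#'
#' @param y observed count image (non-negative integer matrix).
#' @param model a [DegradationModel-class] matching \code{dim(y)}.
#' @param config a [SolverConfig-class].
#' @param verbose print one line per iteration.
#' @return A [RestorationResult-class].
#' @export
dpRestore <- function(y, model, config = solverConfig(), verbose = FALSE) {
  stopifnot(is(model, "DegradationModel"), is(config, "SolverConfig"))
  y <- as.matrix(y)
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers", call. = FALSE)
  if (!all(dim(y) == model@dim)) stop("y does not match the model dimensions", call. = FALSE)
  spec <- config@dpVariant
  bl <- config@betaLambda; bg <- config@betaG; bz <- config@betaZ
  x <- y * 1.0
  rhoLambda <- matrix(0, nrow(y), ncol(y))
  rhoZ <- matrix(0, nrow(y), ncol(y))
  rhoG <- list(h = rhoZ, v = rhoZ)
  gamma <- config@gammaInit
  trace <- vector("list", config@maxIter)
  converged <- FALSE
  k <- 0L
  while (k < config@maxIter) {
    k <- k + 1L
    v <- applyBlur(model, x) + model@background + rhoLambda / bl
    gammaNew <- discrepancyRoot(as.vector(v), as.vector(y), spec,
                                rootTol = config@rootTol, warmStart = gamma,
                                rootSolver = config@rootSolver)
    frozen <- is.na(gammaNew)
    if (!frozen) gamma <- gammaNew
    lambda <- matrix(lambdaClosedForm(gamma, as.vector(v), as.vector(y)),
                     nrow(y), ncol(y))
    w <- .gradForward(x)
    w$h <- w$h + rhoG$h / bg; w$v <- w$v + rhoG$v / bg
    g <- gUpdate(w, bg)
    z <- zUpdate(x + rhoZ / bz)
    xOld <- x
    x <- xUpdate(model, lambda, g, z, rhoLambda, rhoG, rhoZ, bl, bg, bz)
    hx <- applyBlur(model, x) + model@background
    rhoLambda <- rhoLambda - bl * (lambda - hx)
    dx <- .gradForward(x)
    rhoG$h <- rhoG$h - bg * (g$h - dx$h)
    rhoG$v <- rhoG$v - bg * (g$v - dx$v)
    rhoZ <- rhoZ - bz * (z - x)
    nOld <- sqrt(sum(xOld^2))
    epsX <- if (nOld == 0) sqrt(sum(x^2)) else sqrt(sum((x - xOld)^2)) / nOld
    Dval <- .discrepancyD(gamma, as.vector(v), as.vector(y))
    Dtgt <- .discrepancyDelta(gamma, as.vector(v), as.vector(y), spec)
    trace[[k]] <- data.frame(iter = k, gamma = gamma, mu = gamma * bl,
                             discrepancy = Dval, delta = Dtgt,
                             epsX = epsX, frozen = frozen)
    if (verbose)
      message(sprintf("iter %4d  gamma %.4g  D %.6g  Delta %.6g  epsX %.3g%s",
                      k, gamma, Dval, Dtgt, epsX, if (frozen) "  [frozen]" else ""))
    if (!is.finite(epsX))
      stop(errorCondition("DP-ADMM diverged: non-finite relative change",
                          trace = do.call(rbind, trace[seq_len(k)]),
                          class = c("nedpSolverError", "error", "condition")))
    if (epsX < config@tol) { converged <- TRUE; break }
  }
  xHat <- zUpdate(x)
  dx <- .gradForward(x)
  resid <- c(lambda = sqrt(sum((lambda - (applyBlur(model, x) + model@background))^2)),
             g = sqrt(sum((g$h - dx$h)^2) + sum((g$v - dx$v)^2)),
             z = sqrt(sum((z - x)^2)))
  new("RestorationResult", x = xHat, muHat = gamma * bl, gamma = gamma,
      trace = do.call(rbind, trace[seq_len(k)]), iterations = k,
      converged = converged, residuals = resid, config = config, model = model)
}
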
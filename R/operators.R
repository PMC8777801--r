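## Circulant image operators: Gaussian PSF construction, periodic-BC
## convolution diagonalized by the 2-D FFT, and periodic forward-difference
## gradients.  Periodic boundary conditions make blur and difference
## operators block circulant, so all linear solves in the ADMM are exact
## one-FFT operations.

#' Gaussian point-spread function on a square support
#'
#' Samples the isotropic bivariate Gaussian at pixel centers of a
#' \code{band} x \code{band} grid centered at the origin, then normalizes
#' to unit sum (the convention of the usual kernel-generation routines).
#'
#' @param band odd positive integer, side length of the square support in
#'   pixels.
#' @param sigma standard deviation in pixels.
#' @return \code{band} x \code{band} non-negative matrix summing to 1.
#' @export
psfGaussian <- function(band, sigma) {
  if (band < 1 || band %% 2 != 1) stop("band must be an odd positive integer", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  r <- (band - 1) / 2
  u <- seq(-r, r)
  k <- exp(-outer(u^2, u^2, "+") / (2 * sigma^2))
  k / sum(k)
}

## embed a psf (center at its middle pixel) into an n1 x n2 optical
## transfer function: zero-pad, circularly shift the center to (1,1), FFT
.psf2otf <- function(psf, dim) {
  n1 <- dim[1]; n2 <- dim[2]
  if (nrow(psf) > n1 || ncol(psf) > n2) stop("psf larger than image", call. = FALSE)
  pad <- matrix(0, n1, n2)
  pad[seq_len(nrow(psf)), seq_len(ncol(psf))] <- psf
  c1 <- floor(nrow(psf) / 2); c2 <- floor(ncol(psf) / 2)
  shift <- function(m, s1, s2) {
    i <- ((seq_len(nrow(m)) - 1 + s1) %% nrow(m)) + 1
    j <- ((seq_len(ncol(m)) - 1 + s2) %% ncol(m)) + 1
    m[i, j]
  }
  stats::fft(shift(pad, c1, c2))
}

#' Degradation model: periodic blur plus background
#'
#' Encodes the forward operator \eqn{\lambda = H x + b}: circular
#' (periodic-boundary) convolution with a unit-sum PSF, applied through
#' the 2-D FFT, plus a constant non-negative background.  Periodic
#' boundary conditions make \eqn{H} square and diagonal in the Fourier
#' basis, so \eqn{H}, \eqn{H^T} and the ADMM linear system are exact
#' FFT-domain operations.
#'
#' @slot psf unit-sum non-negative kernel.
#' @slot background non-negative scalar emission background.
#' @slot dim image dimensions \code{c(n1, n2)}.
#' @slot otf cached optical transfer function (FFT of the embedded PSF).
#' @seealso [degradationModel()], [applyBlur()]
#' @export
setClass("DegradationModel",
         representation(psf = "matrix", background = "numeric",
                        dim = "integer", otf = "matrix"))

setValidity("DegradationModel", function(object) {
  if (any(object@psf < 0)) return("psf must be non-negative")
  if (abs(sum(object@psf) - 1) > 1e-10) return("psf must sum to 1")
  if (length(object@background) != 1 || object@background < 0)
    return("background must be a non-negative scalar")
  if (length(object@dim) != 2 || any(object@dim < 1)) return("dim must be c(n1, n2)")
  TRUE
})

#' @describeIn DegradationModel-class constructor (precomputes the OTF).
#' @param psf non-negative kernel; normalized to unit sum.
#' @param background non-negative scalar.
#' @param dim image dimensions \code{c(n1, n2)}.
#' @export
degradationModel <- function(psf, background, dim) {
  psf <- psf / sum(psf)
  new("DegradationModel", psf = psf, background = background,
      dim = as.integer(dim), otf = .psf2otf(psf, dim))
}

setMethod("show", "DegradationModel", function(object) {
  cat("DegradationModel:", paste(dim(object@psf), collapse = "x"),
      "psf, background =", object@background, ", image",
      paste(object@dim, collapse = "x"), "\n")
})

#' Apply the blur operator or its adjoint
#'
#' Circular convolution \eqn{Hx} (or \eqn{H^T x}) of an image with the
#' model PSF via the cached OTF; does not add the background.
#'
#' @param model a [DegradationModel-class].
#' @param x matrix of the model's dimensions.
#' @param adjoint apply \eqn{H^T} instead of \eqn{H}.
#' @return Blurred matrix.
#' @export
applyBlur <- function(model, x, adjoint = FALSE) {
  otf <- if (adjoint) Conj(model@otf) else model@otf
  Re(stats::fft(stats::fft(x) * otf, inverse = TRUE)) / length(x)
}

## periodic forward differences and their adjoints; g is stored as a list
## with components h and v (each an n1 x n2 matrix)
.gradForward <- function(x) {
  n2 <- ncol(x); n1 <- nrow(x)
  list(h = x[, c(2:n2, 1), drop = FALSE] - x,
       v = x[c(2:n1, 1), , drop = FALSE] - x)
}

.gradAdjoint <- function(g) {
  n2 <- ncol(g$h); n1 <- nrow(g$h)
  (g$h[, c(n2, 1:(n2 - 1)), drop = FALSE] - g$h) +
    (g$v[c(n1, 1:(n1 - 1)), , drop = FALSE] - g$v)
}

## Fourier eigenvalues of D^T D for an n1 x n2 image (real, >= 0)
.eigDtD <- function(dim) {
  n1 <- dim[1]; n2 <- dim[2]
  wh <- 2 * pi * (seq_len(n2) - 1) / n2
  wv <- 2 * pi * (seq_len(n1) - 1) / n1
  outer(rep(1, n1), abs(exp(1i * wh) - 1)^2) +
    outer(abs(exp(1i * wv) - 1)^2, rep(1, n2))
}

#' Isotropic total variation of an image
#'
#' \eqn{TV(x) = \sum_i \|(Dx)_i\|_2} with periodic forward differences.
#'
#' @param x image matrix.
#' @return Non-negative scalar.
#' @export
totalVariation <- function(x) {
  g <- .gradForward(x)
  sum(sqrt(g$h^2 + g$v^2))
}
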
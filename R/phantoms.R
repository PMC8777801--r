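## Synthetic ground-truth phantoms, the Poisson acquisition simulator, and
## restoration-quality metrics.

#' Synthetic ground-truth phantoms
#'
#' Deterministic (given \code{seed}) test images with values in
#' \eqn{[0, 1]}:
#' \describe{
#'   \item{piecewise_constant}{nested geometric shapes (ellipse,
#'     rectangle, disc, small squares) on a dark background, at most 6
#'     distinct gray levels — a piecewise-constant phantom of the kind TV
#'     regularization favours.}
#'   \item{blobs}{random bright discs on a dark background, emulating
#'     fluorescent cell images.}
#'   \item{ramp}{a smooth diagonal intensity ramp, for smooth-content
#'     tests.}
#' }
#'
#' @param kind phantom type.
#' @param shape image dimensions \code{c(n1, n2)}, each \eqn{\ge 16}.
#' @param seed integer seed (selects gray levels / blob placement).
#' @return Matrix in \eqn{[0, 1]}.
#' @export
makePhantom <- function(kind = c("piecewise_constant", "blobs", "ramp"),
                        shape = c(64, 64), seed = 1L) {
  kind <- match.arg(kind)
  if (length(shape) != 2 || any(shape < 16)) stop("shape must be at least 16x16", call. = FALSE)
  n1 <- shape[1]; n2 <- shape[2]
  set.seed(seed)
  r <- row(matrix(0, n1, n2)) / n1
  c2 <- col(matrix(0, n1, n2)) / n2
  x <- switch(kind,
    piecewise_constant = {
      lev <- sort(sample(seq(0.2, 1, by = 0.1), 4))
      img <- matrix(0, n1, n2)
      img[((r - 0.5) / 0.42)^2 + ((c2 - 0.5) / 0.36)^2 <= 1] <- lev[1]
      img[r > 0.3 & r < 0.7 & c2 > 0.35 & c2 < 0.65] <- lev[2]
      img[(r - 0.5)^2 + (c2 - 0.5)^2 <= 0.12^2] <- lev[3]
      img[r > 0.38 & r < 0.46 & c2 > 0.40 & c2 < 0.48] <- lev[4]
      img[r > 0.56 & r < 0.64 & c2 > 0.54 & c2 < 0.62] <- 0
      img
    },
    blobs = {
      img <- matrix(0, n1, n2)
      nb <- 8L
      cx <- stats::runif(nb, 0.1, 0.9); cy <- stats::runif(nb, 0.1, 0.9)
      rad <- stats::runif(nb, 0.04, 0.12); amp <- stats::runif(nb, 0.4, 1)
      for (b in seq_len(nb))
        img <- pmax(img, amp[b] * ((r - cx[b])^2 + (c2 - cy[b])^2 <= rad[b]^2))
      img
    },
    ramp = (r + c2) / 2)
  pmin(pmax(x, 0), 1)
}

#' Acquisition specification
#'
#' Parameters of the simulated acquisition protocol: the ground-truth
#' image (values in \eqn{[0,1]}) is scaled by the maximum expected photon
#' count \eqn{\kappa}, blurred by a unit-sum Gaussian PSF with periodic
#' boundary conditions, a constant emission background \eqn{b} is added,
#' and independent Poisson counts are drawn.
#'
#' @slot kappa positive integer, maximum expected photon count.
#' @slot band odd positive integer, PSF support side (pixels).
#' @slot sigma positive PSF standard deviation (pixels).
#' @slot background non-negative constant emission background.
#' @slot seed integer seed for the Poisson draw.
#' @export
setClass("AcquisitionSpec",
         representation(kappa = "numeric", band = "integer", sigma = "numeric",
                        background = "numeric", seed = "integer"))

setValidity("AcquisitionSpec", function(object) {
  if (object@kappa < 1 || object@kappa != round(object@kappa))
    return("kappa must be a positive integer")
  if (object@band < 1 || object@band %% 2 != 1) return("band must be odd and positive")
  if (object@sigma <= 0) return("sigma must be positive")
  if (object@background < 0) return("background must be non-negative")
  TRUE
})

#' @describeIn AcquisitionSpec-class constructor with the standard
#'   defaults (mild blur, background \eqn{2\times 10^{-3}}).
#' @param kappa maximum expected photon count.
#' @param band,sigma Gaussian PSF parameters.
#' @param background constant emission background.
#' @param seed Poisson-draw seed.
#' @export
acquisitionSpec <- function(kappa = 5, band = 5L, sigma = 1, background = 2e-3,
                            seed = 1L) {
  new("AcquisitionSpec", kappa = kappa, band = as.integer(band), sigma = sigma,
      background = background, seed = as.integer(seed))
}

setMethod("show", "AcquisitionSpec", function(object) {
  cat("AcquisitionSpec: kappa =", object@kappa, ", psf band =", object@band,
      "sigma =", object@sigma, ", background =", object@background,
      ", seed =", object@seed, "\n")
})

#' Simulate the blurred Poisson acquisition
#'
#' \eqn{\bar\lambda = H(\kappa\, x) + b} (periodic-BC Gaussian blur) and
#' \eqn{y \sim \mathrm{Poisson}(\bar\lambda)} drawn independently per
#' pixel with the spec's seed.  Varying only the seed changes \eqn{y} but
#' not \eqn{\bar\lambda}.
#'
#' @param xTrue ground-truth image in \eqn{[0, 1]}.
#' @param spec an [AcquisitionSpec-class].
#' @return \code{list(y =, lambdaBar =, model =)} where \code{model} is
#'   the [DegradationModel-class] used.
#' @export
degrade <- function(xTrue, spec = acquisitionSpec()) {
  stopifnot(is(spec, "AcquisitionSpec"))
  if (min(xTrue) < 0 || max(xTrue) > 1) stop("xTrue must lie in [0, 1]", call. = FALSE)
  model <- degradationModel(psfGaussian(spec@band, spec@sigma),
                            spec@background, dim(xTrue))
  lambdaBar <- applyBlur(model, spec@kappa * xTrue) + spec@background
  lambdaBar <- pmax(lambdaBar, 0)   # clip tiny negative FFT round-off
  set.seed(spec@seed)
  y <- matrix(stats::rpois(length(lambdaBar), as.vector(lambdaBar)),
              nrow(lambdaBar), ncol(lambdaBar))
  list(y = y, lambdaBar = lambdaBar, model = model)
}

#' Improved signal-to-noise ratio
#'
#' \eqn{\mathrm{ISNR}(\hat x, \bar x) = 10 \log_{10}
#' \left(\|\bar x - b\|_2^2 / \|\bar x - \hat x\|_2^2\right)} in dB, with
#' the background \eqn{b} broadcast as a constant.  \code{Inf} for an
#' exact restoration.
#'
#' @param xHat restored image.
#' @param xTrue ground-truth image of the same shape.
#' @param background constant background \eqn{b}.
#' @return Scalar in dB.
#' @export
isnr <- function(xHat, xTrue, background = 0) {
  if (!all(dim(xHat) == dim(xTrue))) stop("shapes must match", call. = FALSE)
  10 * log10(sum((xTrue - background)^2) / sum((xTrue - xHat)^2))
}

## circular 2-D convolution with a small separable Gaussian window
.gaussFilter <- function(x, win, sigma) {
  u <- seq(-(win - 1) / 2, (win - 1) / 2)
  k <- exp(-u^2 / (2 * sigma^2)); k <- k / sum(k)
  n1 <- nrow(x); n2 <- ncol(x)
  kr <- numeric(n1); kr[(seq_along(k) - 1 - (win - 1) / 2) %% n1 + 1] <- k
  kc <- numeric(n2); kc[(seq_along(k) - 1 - (win - 1) / 2) %% n2 + 1] <- k
  f <- Re(stats::fft(stats::fft(x) * outer(stats::fft(kr), stats::fft(kc)),
                     inverse = TRUE)) / (n1 * n2)
  f
}

#' Structural similarity index
#'
#' Standard SSIM with the conventional defaults: 11x11 Gaussian window of
#' standard deviation 1.5, stabilizers \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 =
#' (0.03 L)^2} for data range \eqn{L}.  Local statistics are computed with
#' periodic filtering; a border of half the window width is excluded from
#' the average.
#'
#' @param x1,x2 images of the same shape.
#' @param dataRange dynamic range \eqn{L} (default 1 for \eqn{[0,1]}
#'   images).
#' @return Scalar in \eqn{[-1, 1]}; 1 iff the images are identical.
#' @export
ssim <- function(x1, x2, dataRange = 1) {
  if (!all(dim(x1) == dim(x2))) stop("shapes must match", call. = FALSE)
  win <- 11L; sg <- 1.5
  C1 <- (0.01 * dataRange)^2; C2 <- (0.03 * dataRange)^2
  mu1 <- .gaussFilter(x1, win, sg); mu2 <- .gaussFilter(x2, win, sg)
  s11 <- .gaussFilter(x1 * x1, win, sg) - mu1^2
  s22 <- .gaussFilter(x2 * x2, win, sg) - mu2^2
  s12 <- .gaussFilter(x1 * x2, win, sg) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  b <- (win - 1) / 2
  n1 <- nrow(x1); n2 <- ncol(x1)
  if (n1 > 2 * b && n2 > 2 * b)
    map <- map[(b + 1):(n1 - b), (b + 1):(n2 - b)]
  mean(map)
}
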
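## Image and configuration I/O plus the end-to-end experiment driver.

#' Read a grayscale image from PNG or TIFF
#'
#' Returns the image as a matrix with rows indexing image rows.  RGB(A)
#' inputs are converted to luminance (0.299 R + 0.587 G + 0.114 B) with a
#' warning.  With \code{type = "counts"}, pixel values are mapped back to
#' the integers encoded by [saveImage()] (16-bit scale).
#'
#' @param path file ending in \code{.png}, \code{.tif} or \code{.tiff}.
#' @param type \code{"intensity"} (float in \eqn{[0,1]}) or
#'   \code{"counts"} (non-negative integers).
#' @return Matrix with attributes \code{bitDepth} and \code{source}.
#' @export
loadImage <- function(path, type = c("intensity", "counts")) {
  type <- match.arg(type)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path, info = TRUE),
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    stop("unsupported image format: ", ext, call. = FALSE))
  info <- attributes(img)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) {
      warning("multichannel image: converting to luminance")
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else img <- img[, , 1]
  }
  bits <- if (!is.null(info$info$bit.depth)) info$info$bit.depth
          else if (!is.null(info$bits.per.sample)) info$bits.per.sample else NA
  img <- as.matrix(img)
  if (type == "counts") img <- round(img * 65535)
  attr(img, "bitDepth") <- bits
  attr(img, "source") <- path
  img
}

#' Write a grayscale image as PNG or TIFF
#'
#' Intensities are written as 8-bit PNG or 32-bit float TIFF depending on
#' the extension; count images (\code{type = "counts"}) are stored exactly
#' as \code{value / 65535} in 16-bit TIFF, so integers up to 65535 round
#' trip bit-exactly through [loadImage()].
#'
#' @param x image matrix.
#' @param path output path (\code{.png}, \code{.tif}/\code{.tiff}).
#' @param type see [loadImage()].
#' @return \code{path}, invisibly.
#' @export
saveImage <- function(x, path, type = c("intensity", "counts")) {
  type <- match.arg(type)
  ext <- tolower(tools::file_ext(path))
  if (type == "counts") {
    if (any(x < 0) || any(x != round(x)) || any(x > 65535))
      stop("counts must be integers in [0, 65535]", call. = FALSE)
    if (!ext %in% c("tif", "tiff"))
      stop("count images are stored as 16-bit TIFF; use a .tif/.tiff path",
           call. = FALSE)
    tiff::writeTIFF(x / 65535, path, bits.per.sample = 16, reduce = FALSE)
    return(invisible(path))
  }
  x <- pmin(pmax(x, 0), 1)
  switch(ext,
    png = png::writePNG(x, path, dpi = NULL),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 32, reduce = FALSE),
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

#' Read / write a run configuration
#'
#' A run configuration is a plain named list fully describing an
#' experiment (phantom, acquisition, solver and calibration settings plus
#' seeds), serializable to a single YAML document so that a run can be
#' replayed exactly from its config.  See [runExperiment()] for the
#' recognized fields.
#'
#' @param path YAML file path.
#' @param config named list.
#' @return \code{readRunConfig}: the list; \code{writeRunConfig}:
#'   \code{path}, invisibly.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.configDefaults <- function(config) {
  utils::modifyList(list(
    phantom = list(kind = "piecewise_constant", shape = c(64, 64), seed = 1),
    kappa = 5, band = 5, sigma = 1, background = 2e-3,
    noiseSeeds = 1,
    variants = c("adp", "nedp"),
    betaLambda = 1, betaG = 1, betaZ = 1,
    tol = 1e-5, maxIter = 500, rootTol = 1e-6),
    config)
}

.variantSpec <- function(name, lambdaBar) {
  switch(name,
    adp = deltaSpec("approximate"),
    nedp = deltaSpec("nearly_exact"),
    tdp = deltaSpec("theoretical", referenceLambda = as.vector(lambdaBar)),
    stop("unknown DP variant: ", name, call. = FALSE))
}

#' Run a simulate / restore / evaluate experiment
#'
#' For each photon-count level \eqn{\kappa}, each noise seed and each
#' discrepancy-principle variant (\code{"adp"}, \code{"nedp"},
#' \code{"tdp"}), generates the phantom, simulates the acquisition,
#' restores with [dpRestore()] and evaluates ISNR and SSIM against the
#' normalized ground truth.  The restored image is rescaled by
#' \eqn{1/\kappa} before comparison so metrics refer to the \eqn{[0,1]}
#' ground truth.
#'
#' @param config named list (see [readRunConfig()]); missing fields take
#'   defaults (64x64 piecewise-constant phantom, \eqn{\kappa = 5}, mild
#'   blur, variants adp + nedp).
#' @param outDir optional directory: writes \code{results.csv}, per-run
#'   traces and the replayed config.
#' @param verbose print progress lines.
#' @return data.frame with columns \code{variant}, \code{kappa},
#'   \code{seed}, \code{mu_hat}, \code{isnr}, \code{ssim},
#'   \code{iterations}.
#' @export
runExperiment <- function(config = list(), outDir = NULL, verbose = FALSE) {
  cfg <- .configDefaults(config)
  xTrue <- makePhantom(cfg$phantom$kind, unlist(cfg$phantom$shape),
                       seed = cfg$phantom$seed)
  rows <- list()
  traces <- list()
  for (kappa in cfg$kappa) for (sd in cfg$noiseSeeds) {
    acq <- acquisitionSpec(kappa = kappa, band = cfg$band, sigma = cfg$sigma,
                           background = cfg$background, seed = sd)
    sim <- degrade(xTrue, acq)
    for (vn in cfg$variants) {
      sc <- solverConfig(dpVariant = .variantSpec(vn, sim$lambdaBar),
                         betaLambda = cfg$betaLambda, betaG = cfg$betaG,
                         betaZ = cfg$betaZ, tol = cfg$tol,
                         maxIter = cfg$maxIter, rootTol = cfg$rootTol,
                         seed = sd)
      res <- dpRestore(sim$y, sim$model, sc)
      xr <- restoredImage(res) / kappa
      rows[[length(rows) + 1]] <- data.frame(
        variant = vn, kappa = kappa, seed = sd, mu_hat = muHat(res),
        isnr = isnr(xr, xTrue, cfg$background),
        ssim = ssim(xr, xTrue), iterations = res@iterations)
      traces[[sprintf("%s_k%g_s%d", vn, kappa, sd)]] <- solverTrace(res)
      if (verbose)
        message(sprintf("%s kappa=%g seed=%d: mu=%.4g isnr=%.2f iters=%d",
                        vn, kappa, sd, muHat(res),
                        rows[[length(rows)]]$isnr, res@iterations))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(outDir, "results.csv"), row.names = FALSE)
    writeRunConfig(cfg, file.path(outDir, "config.yaml"))
    for (nm in names(traces))
      utils::write.csv(traces[[nm]],
                       file.path(outDir, paste0("trace_", nm, ".csv")),
                       row.names = FALSE)
  }
  out
}
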
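#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 2, neither constant.
#' @return numeric(1) correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2) stop("need at least 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(x, y)
}

#' Pixel-by-pixel correlation of an image with a reference spectrum
#'
#' The reference is resampled onto the image axis, both are restricted to
#' `[lo, hi]` (defaults to the full image axis), and every unmasked pixel is
#' correlated with the reference. Constant pixels are recorded as NA
#' (masked); the display map clips negatives to 0 to match the 0 (dark) to 1
#' (white) convention.
#'
#' @param img a [SpectralImage-class].
#' @param ref reference [Spectrum-class] (e.g. type I collagen).
#' @param lo,hi wavenumber range (cm^-1); NULL = full image axis.
#' @param mode label recorded in the map ("raw" for atmospheric-corrected
#'   input, "dewaxed" for EMSC-corrected input).
#' @return a [CorrelationMap-class].
#' @export
correlateImage <- function(img, ref, lo = NULL, hi = NULL, mode = "raw") {
  stopifnot(is(img, "SpectralImage"), is(ref, "Spectrum"))
  if (is.null(lo)) lo <- min(img@axis)
  if (is.null(hi)) hi <- max(img@axis)
  sub <- cropSpectralRange(img, lo, hi)
  refR <- resampleToAxis(ref, sub@axis)
  Y <- pixelMatrix(sub)
  idx <- attr(Y, "pixelIndex")
  d <- dim(img@cube)
  rRaw <- matrix(NA_real_, d[1], d[2])
  if (nrow(Y)) {
    yc <- refR@absorbance - mean(refR@absorbance)
    ny <- sqrt(sum(yc^2))
    if (ny == 0) stop("reference spectrum is constant on the range")
    Xc <- Y - rowMeans(Y)
    nx <- sqrt(rowSums(Xc^2))
    r <- as.vector(Xc %*% yc) / (nx * ny)
    r[nx == 0] <- NA_real_ # constant pixels: correlation undefined, masked
    r <- pmin(pmax(r, -1), 1)
    rRaw[idx[, 1] + (idx[, 2] - 1L) * d[1]] <- r
  }
  new("CorrelationMap", rRaw = rRaw, rDisplay = pmin(pmax(rRaw, 0), 1),
      range = c(lo, hi), mode = mode)
}

#' Render a correlation map as a grayscale PNG
#'
#' Display values map linearly to 8-bit gray: `round(255 * r)`, 0 = black,
#' 1 = white; masked/undefined pixels render black.
#'
#' @param map a [CorrelationMap-class].
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
renderCorrelation <- function(map, path) {
  stopifnot(is(map, "CorrelationMap"))
  g <- map@rDisplay
  g[is.na(g)] <- 0
  png::writePNG(round(255 * g) / 255, target = path)
  invisible(path)
}
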
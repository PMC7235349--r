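#' Assemble an EMSC basis
#'
#' Builds and validates the least-squares design
#' `[target | interference spectra | polynomial terms]`. Rank deficiency is
#' an explicit error naming the culprit columns; it is never papered over
#' with a pseudo-inverse.
#'
#' @param target [Spectrum-class] tissue reference `m`.
#' @param interference list of [Spectrum-class] on the same axis.
#' @param polyOrder polynomial baseline order (>= 0).
#' @return an [EMSCBasis-class].
#' @export
emscBasis <- function(target, interference = list(), polyOrder = 2) {
  stopifnot(is(target, "Spectrum"))
  axis <- target@axis
  for (s in interference) {
    stopifnot(is(s, "Spectrum"))
    if (!identical(s@axis, axis))
      stop("interference spectrum '", s@name, "' is not on the target axis")
  }
  D <- cbind(target@absorbance,
             if (length(interference))
               vapply(interference, function(s) s@absorbance,
                      numeric(length(axis))),
             polyTerms(axis, polyOrder))
  colnames(D) <- c("target",
                   if (length(interference))
                     sprintf("interference%d", seq_along(interference)),
                   sprintf("poly%d", 0:polyOrder))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    culprit <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("collinearity error: EMSC design is rank deficient; culprit ",
         "column(s): ", paste(culprit, collapse = ", "))
  }
  new("EMSCBasis", target = target, interference = interference,
      polyOrder = as.integer(polyOrder), axis = axis, design = D)
}

#' Build a dewaxing basis from a pure-paraffin image
#'
#' The interference block is the mean paraffin pixel spectrum followed by the
#' first `nComponents` principal-component loadings of the mean-centred
#' paraffin pixel spectra (decreasing explained variance; sign fixed so each
#' loading's largest-magnitude element is positive). Polynomial terms are
#' powers of the axis rescaled to [-1, 1].
#'
#' @param paraffinImg [SpectralImage-class] of pure paraffin.
#' @param nComponents number of principal components (>= 0, default 8).
#' @param polyOrder polynomial baseline order (default 2).
#' @param target [Spectrum-class] tissue reference; resampled to the paraffin
#'   axis if needed.
#' @return an [EMSCBasis-class].
#' @export
buildParaffinBasis <- function(paraffinImg, nComponents = 8, polyOrder = 2,
                               target) {
  stopifnot(is(paraffinImg, "SpectralImage"), is(target, "Spectrum"),
            nComponents >= 0)
  axis <- paraffinImg@axis
  if (!identical(target@axis, axis)) target <- resampleToAxis(target, axis)
  X <- pixelMatrix(paraffinImg)
  if (nrow(X) < 1) stop("paraffin image has no unmasked pixels")
  meanSpec <- colMeans(X)
  interference <- list(Spectrum(axis, meanSpec, "paraffin_mean"))
  if (nComponents > 0) {
    if (nComponents >= nrow(X))
      stop("rank error: ", nComponents, " components requested from only ",
           nrow(X), " paraffin pixels")
    ctr <- sweep(X, 2, meanSpec)
    sv <- svd(ctr, nu = 0, nv = nComponents)
    tol <- max(dim(ctr)) * .Machine$double.eps * max(sv$d, 0)
    if (sum(sv$d > tol) < nComponents)
      stop("rank error: paraffin image supports only ", sum(sv$d > tol),
           " principal components (zero variance beyond that)")
    for (j in seq_len(nComponents)) {
      v <- sv$v[, j]
      if (v[which.max(abs(v))] < 0) v <- -v
      interference[[j + 1L]] <- Spectrum(axis, v, sprintf("paraffin_pc%d", j))
    }
  }
  emscBasis(target, interference, polyOrder)
}

# Fit coefficients for a matrix of spectra (rows = pixels) against a basis.
# Returns coefficient matrix (pixels x columns) and residual RMS per pixel.
emscFitMatrix <- function(Y, basis) {
  if (!all(is.finite(Y))) stop("data error: non-finite absorbance values")
  D <- basis@design
  qrD <- qr(D)
  coef <- t(qr.coef(qrD, t(Y)))
  resid <- Y - tcrossprod(coef, D)
  list(coef = coef, residualRms = sqrt(rowMeans(resid^2)))
}

#' Fit the EMSC model to one spectrum
#'
#' Ordinary least squares of `s ~ c*m + sum(b_i p_i) + sum(d_j q_j)` solved
#' by QR factorisation (matches the normal equations to 1e-8 on
#' well-conditioned designs).
#'
#' @param s a [Spectrum-class] on the basis axis.
#' @param basis an [EMSCBasis-class].
#' @return an [EMSCFit-class] with scale `c`, interference coefficients `b`,
#'   baseline coefficients `d` and the residual RMS.
#' @export
fitEMSC <- function(s, basis) {
  stopifnot(is(s, "Spectrum"), is(basis, "EMSCBasis"))
  if (!identical(s@axis, basis@axis))
    stop("spectrum is not on the basis axis")
  fit <- emscFitMatrix(matrix(s@absorbance, nrow = 1), basis)
  nInt <- length(basis@interference)
  co <- unname(fit$coef[1, ])
  new("EMSCFit", c = co[1], b = if (nInt) co[1 + seq_len(nInt)] else numeric(),
      d = co[(2 + nInt - 1) + seq_len(basis@polyOrder + 1)],
      residualRms = fit$residualRms[1])
}

#' Apply an EMSC correction to one spectrum
#'
#' `corrected = (s - sum(b_i p_i) - sum(d_j q_j)) / c`: interference and
#' baseline removed, thickness rescaled to unit scale; the residual (the
#' tissue variability around the target) is retained.
#'
#' @param s the original [Spectrum-class].
#' @param fit its [EMSCFit-class].
#' @param basis the [EMSCBasis-class] used for the fit.
#' @param rule a [MaskRule-class]; |c| below `rule@cMin` is a degenerate
#'   pixel and raises an error (callers mask such pixels instead).
#' @return the corrected [Spectrum-class].
#' @export
correctSpectrum <- function(s, fit, basis, rule = maskRule()) {
  stopifnot(is(fit, "EMSCFit"))
  if (abs(fit@c) < rule@cMin)
    stop("degenerate-pixel error: |c| = ", signif(abs(fit@c), 3),
         " below cMin = ", rule@cMin)
  D <- basis@design
  nuisance <- D[, -1, drop = FALSE] %*% c(fit@b, fit@d)
  Spectrum(basis@axis, (s@absorbance - as.vector(nuisance)) / fit@c, s@name)
}

# Unmasked pixel spectra of an image as a matrix (pixels x channels), with
# the pixel (row, col) index of each matrix row.
pixelMatrix <- function(img) {
  d <- dim(img@cube)
  Y <- matrix(img@cube, nrow = d[1] * d[2])
  sel <- which(as.vector(img@mask))
  Y <- Y[sel, , drop = FALSE]
  attr(Y, "pixelIndex") <- arrayInd(sel, d[1:2])
  Y
}

#' Mean tissue spectrum of an image
#'
#' Default policy for choosing the EMSC target `m`: the element-wise mean
#' over unmasked pixels.
#'
#' @param img a [SpectralImage-class].
#' @param name name for the returned spectrum.
#' @return a [Spectrum-class].
#' @export
chooseTarget <- function(img, name = "mean_tissue") {
  X <- pixelMatrix(img)
  if (nrow(X) == 0) stop("empty mask: no pixels to average")
  Spectrum(img@axis, colMeans(X), name)
}

#' Digitally dewax a spectral image
#'
#' Crops (and, if the grids differ, linearly resamples) the image to the
#' basis axis, fits the EMSC model to every unmasked pixel, masks pixels that
#' fail the rule (blank paraffin: fitted |c| < cMin; outliers: residual RMS
#' above `residualMax`), and corrects the rest. Masked pixels are zeroed in
#' the output cube.
#'
#' @param img a [SpectralImage-class] whose axis covers the basis axis.
#' @param basis an [EMSCBasis-class].
#' @param rule a [MaskRule-class].
#' @return a list with `image` (corrected [SpectralImage-class] on the basis
#'   axis), `c` (fitted scale map), `b` (rows x cols x n_interference array
#'   of paraffin coefficients) and `residualRms` (map, AU). Emits a warning
#'   (not an error) if no pixel survives the rule.
#' @export
dewaxImage <- function(img, basis, rule = maskRule()) {
  stopifnot(is(img, "SpectralImage"), is(basis, "EMSCBasis"))
  axis <- basis@axis
  if (!identical(img@axis, axis)) {
    rng <- range(axis)
    sub <- cropSpectralRange(img, rng[1], rng[2])
    if (identical(sub@axis, axis)) {
      img <- sub
    } else {
      w <- interpWeights(img@axis, axis)
      d <- dim(img@cube)
      Yall <- matrix(img@cube, nrow = d[1] * d[2])
      Yres <- Yall[, w$i1, drop = FALSE] * rep(w$w1, each = nrow(Yall)) +
        Yall[, w$i2, drop = FALSE] * rep(w$w2, each = nrow(Yall))
      img <- SpectralImage(axis, array(Yres, c(d[1], d[2], length(axis))),
                           img@pixelSize, img@mask, img@meta)
    }
  }
  d <- dim(img@cube)
  Y <- pixelMatrix(img)
  idx <- attr(Y, "pixelIndex")
  fit <- emscFitMatrix(Y, basis)
  nInt <- length(basis@interference)
  cVec <- fit$coef[, 1]
  keep <- abs(cVec) >= rule@cMin & fit$residualRms <= rule@residualMax
  if (!any(keep))
    warning("all pixels masked: no tissue pixel passed the mask rule")

  D <- basis@design
  nuis <- tcrossprod(fit$coef[, -1, drop = FALSE], D[, -1, drop = FALSE])
  corr <- (Y - nuis) / cVec

  n <- length(axis)
  cube <- array(0, dim = c(d[1], d[2], n))
  cMap <- matrix(NA_real_, d[1], d[2])
  resMap <- matrix(NA_real_, d[1], d[2])
  bArr <- array(NA_real_, dim = c(d[1], d[2], nInt))
  mask <- matrix(FALSE, d[1], d[2])
  flat <- idx[, 1] + (idx[, 2] - 1L) * d[1]
  cMap[flat] <- cVec
  resMap[flat] <- fit$residualRms
  for (j in seq_len(nInt))
    bArr[flat + (j - 1L) * d[1] * d[2]] <- fit$coef[, 1 + j]
  keepFlat <- flat[keep]
  mask[keepFlat] <- TRUE
  for (ch in seq_len(n))
    cube[keepFlat + (ch - 1L) * d[1] * d[2]] <- corr[keep, ch]
  out <- SpectralImage(axis, cube, img@pixelSize, mask,
                       c(img@meta, list(dewaxed = "true")))
  list(image = out, c = cMap, b = bArr, residualRms = resMap)
}
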
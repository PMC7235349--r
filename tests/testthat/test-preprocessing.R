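makeBasisFixture <- function(nComponents = 1, polyOrder = 2, seed = 11) {
  axis <- makeAxis(1800, 800, 2)
  target <- buildEndmember(defaultEndmembers()$dermis, axis)
  par <- cropSpectralRange(simulateParaffinImage(makeAxis(), seed = seed),
                           800, 1800)
  buildParaffinBasis(par, nComponents, polyOrder, target)
}

test_that("paraffin basis: mean spectrum, PCA loadings and rank checks", {
  axis <- makeAxis(1800, 800, 2)
  target <- buildEndmember(defaultEndmembers()$dermis, axis)
  # constant paraffin image: mean recovered, any PC request is a rank error
  P <- absorbances(buildEndmember(paraffinEndmember(), axis))
  cube <- array(rep(P, each = 9), c(3, 3, length(axis)))
  flat <- SpectralImage(axis, cube)
  b0 <- buildParaffinBasis(flat, 0, 2, target)
  expect_length(b0@interference, 1)
  expect_equal(absorbances(b0@interference[[1]]), P, ignore_attr = TRUE)
  expect_error(buildParaffinBasis(flat, 1, 2, target), "rank error")
  # more components than pixels
  expect_error(buildParaffinBasis(flat, 9, 2, target), "rank error")

  # loadings match an independent covariance eigendecomposition oracle
  par <- cropSpectralRange(
    simulateParaffinImage(makeAxis(), rows = 10, cols = 5, seed = 4),
    800, 1800)
  basis <- buildParaffinBasis(par, 2, 2, target)
  X <- matrix(absorbances(par), nrow = 50)
  ctr <- sweep(X, 2, colMeans(X))
  eig <- eigen(crossprod(ctr), symmetric = TRUE)
  for (j in 1:2) {
    v <- eig$vectors[, j]
    got <- absorbances(basis@interference[[j + 1]])
    expect_lt(min(max(abs(got - v)), max(abs(got + v))), 1e-8)
  }
})

test_that("EMSC fits recover known coefficients and match normal equations", {
  basis <- makeBasisFixture()
  axis <- basis@axis
  m <- absorbances(basis@target)
  p1 <- absorbances(basis@interference[[1]])
  x <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1

  f <- fitEMSC(Spectrum(axis, m, "m"), basis)
  expect_equal(f@c, 1, tolerance = 1e-10)
  expect_lt(max(abs(c(f@b, f@d))), 1e-10)
  expect_lt(f@residualRms, 1e-10)

  f2 <- fitEMSC(Spectrum(axis, 2 * m, "2m"), basis)
  expect_equal(f2@c, 2, tolerance = 1e-10)
  expect_lt(max(abs(c(f2@b, f2@d))), 1e-10)

  s <- m + 0.5 * p1 + 0.1 + 0.05 * x
  f3 <- fitEMSC(Spectrum(axis, s, "mix"), basis)
  expect_equal(f3@c, 1, tolerance = 1e-8)
  expect_equal(f3@b[1], 0.5, tolerance = 1e-8)
  expect_equal(unname(f3@d[1:2]), c(0.1, 0.05), tolerance = 1e-8)

  # independent normal-equations oracle on a random target vector
  set.seed(8)
  y <- m + rnorm(length(m), sd = 0.01)
  fy <- fitEMSC(Spectrum(axis, y, "y"), basis)
  D <- basis@design
  beta <- solve(crossprod(D), crossprod(D, y))
  expect_lt(max(abs(c(fy@c, fy@b, fy@d) - as.vector(beta))), 1e-8)
})

test_that("corrected spectra invert the fitted nuisance exactly", {
  basis <- makeBasisFixture()
  axis <- basis@axis
  m <- absorbances(basis@target)
  p1 <- absorbances(basis@interference[[1]])

  s <- Spectrum(axis, m, "m")
  corr <- correctSpectrum(s, fitEMSC(s, basis), basis)
  expect_equal(absorbances(corr), m, tolerance = 1e-12, ignore_attr = TRUE)

  s2 <- Spectrum(axis, 3 * m + p1, "mix")
  corr2 <- correctSpectrum(s2, fitEMSC(s2, basis), basis)
  expect_lt(max(abs(absorbances(corr2) - m)), 1e-10)

  # degenerate pixel: scale below the mask threshold
  s3 <- Spectrum(axis, 0.01 * m + p1, "blank")
  f3 <- fitEMSC(s3, basis)
  expect_error(correctSpectrum(s3, f3, basis, maskRule(cMin = 0.2)),
               "degenerate-pixel")
})

test_that("fits are equivariant under positive scaling of the input", {
  basis <- makeBasisFixture()
  axis <- basis@axis
  set.seed(3)
  y <- absorbances(basis@target) +
    0.3 * absorbances(basis@interference[[1]]) + rnorm(length(axis), sd = 0.01)
  f1 <- fitEMSC(Spectrum(axis, y, "y"), basis)
  f2 <- fitEMSC(Spectrum(axis, 2.5 * y, "y2"), basis)
  expect_equal(f2@c, 2.5 * f1@c, tolerance = 1e-9)
  expect_equal(f2@b, 2.5 * f1@b, tolerance = 1e-9)
  expect_equal(f2@d, 2.5 * f1@d, tolerance = 1e-9)
  c1 <- correctSpectrum(Spectrum(axis, y, "y"), f1, basis)
  c2 <- correctSpectrum(Spectrum(axis, 2.5 * y, "y2"), f2, basis)
  expect_equal(absorbances(c1), absorbances(c2), tolerance = 1e-9)
})

test_that("dewaxing a noiseless phantom recovers clean endmembers and masks blanks", {
  cfg <- phantomConfig(rows = 12, cols = 12, nHairBulbs = 0,
                       paraffinAmplitudeMean = 0.5, paraffinAmplitudeSd = 0.2,
                       baselineOrder = 2, baselineAmplitude = 0.05,
                       thicknessSd = 0.1, noiseSd = 0, seed = 6)
  ph <- generatePhantom(cfg)
  img <- cropSpectralRange(ph@image, 800, 1800)
  axis <- wavenumbers(img)
  par <- cropSpectralRange(simulateParaffinImage(makeAxis(), seed = 2,
                                                 noiseSd = 0), 800, 1800)
  target <- buildEndmember(defaultEndmembers()$dermis, axis)
  basis <- buildParaffinBasis(par, 1, 2, target)
  dw <- dewaxImage(img, basis, maskRule(0.2))
  dsel <- labelMatrix(ph@truth) == 1L
  Y <- matrix(absorbances(dw$image), nrow = 144)
  dev <- abs(Y[as.vector(dsel), ] -
               matrix(absorbances(target), sum(dsel), length(axis),
                      byrow = TRUE))
  expect_lt(max(dev), 1e-8)
  # fitted scale approximates true thickness on dermis pixels
  expect_equal(dw$c[dsel], ph@trueThickness[dsel], tolerance = 1e-6)

  # blank pixels: pure paraffin carries no tissue scale and is masked
  P <- absorbances(buildEndmember(paraffinEndmember(), axis))
  blank <- SpectralImage(axis, array(rep(P * 0.8, each = 4),
                                     c(2, 2, length(axis))))
  expect_warning(dwb <- dewaxImage(blank, basis, maskRule(0.2)),
                 "all pixels masked")
  expect_true(all(!tissueMask(dwb$image)))
  expect_true(all(abs(dwb$c) < 0.2))
})

test_that("dewaxing an already-dewaxed image is a fixed point", {
  cfg <- phantomConfig(rows = 10, cols = 10, nHairBulbs = 0,
                       paraffinAmplitudeMean = 0.4, noiseSd = 0, seed = 9)
  ph <- generatePhantom(cfg)
  img <- cropSpectralRange(ph@image, 800, 1800)
  par <- cropSpectralRange(simulateParaffinImage(makeAxis(), seed = 2,
                                                 noiseSd = 0), 800, 1800)
  target <- buildEndmember(defaultEndmembers()$dermis, axis <- wavenumbers(img))
  basis <- buildParaffinBasis(par, 1, 2, target)
  once <- dewaxImage(img, basis, maskRule(0.2))
  dsel <- as.vector(labelMatrix(ph@truth) == 1L & tissueMask(once$image))
  twice <- dewaxImage(once$image, basis, maskRule(0.2))
  expect_lt(max(abs(twice$c[dsel] - 1)), 1e-6)
  expect_lt(max(abs(twice$b[, , 1][matrix(dsel, 10, 10)])), 1e-6)
})

test_that("choose_target averages unmasked pixels element-wise", {
  axis <- makeAxis(1100, 1000, 10)
  n <- length(axis)
  set.seed(2)
  cube <- array(rnorm(10 * n), c(2, 5, n))
  img <- SpectralImage(axis, cube)
  tgt <- chooseTarget(img)
  oracle <- apply(matrix(cube, nrow = 10), 2, mean)
  expect_identical(absorbances(tgt), oracle)

  # uniform image: target equals any pixel
  u <- rnorm(n)
  uni <- SpectralImage(axis, array(rep(u, each = 4), c(2, 2, n)))
  expect_equal(absorbances(chooseTarget(uni)), u, tolerance = 1e-12)

  img@mask[] <- FALSE
  expect_error(chooseTarget(img), "empty mask")
})

test_that("corrected spectra stay within twice the noise level under noise", {
  cfg <- phantomConfig(rows = 24, cols = 24, nHairBulbs = 0,
                       paraffinAmplitudeMean = 0.5, paraffinAmplitudeSd = 0.2,
                       baselineAmplitude = 0.05, noiseSd = 0.005, seed = 13)
  ph <- generatePhantom(cfg)
  img <- cropSpectralRange(ph@image, 800, 1800)
  axis <- wavenumbers(img)
  par <- cropSpectralRange(simulateParaffinImage(makeAxis(), seed = 2),
                           800, 1800)
  target <- buildEndmember(defaultEndmembers()$dermis, axis)
  basis <- buildParaffinBasis(par, 1, 2, target)
  dw <- dewaxImage(img, basis, maskRule(0.2))
  dsel <- as.vector(labelMatrix(ph@truth) == 1L)
  Y <- matrix(absorbances(dw$image), nrow = 576)[dsel, ]
  clean <- matrix(absorbances(target), sum(dsel), length(axis), byrow = TRUE)
  rmse <- sqrt(rowMeans((Y - clean)^2))
  expect_lt(median(rmse), 2 * 0.005)
})
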
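test_that("HDF5 container round-trips axis, cube, mask and metadata", {
  cfg <- cleanConfig(rows = 4, cols = 4, seed = 3)
  ph <- generatePhantom(cfg)
  img <- ph@image
  img@meta <- list(sample_id = "s1", group = "WT", note = "fixture")
  f <- tempfile(fileext = ".h5")
  saveImage(img, f)
  back <- loadImage(f)
  expect_identical(wavenumbers(back), wavenumbers(img))
  expect_identical(absorbances(back), absorbances(img))
  expect_identical(tissueMask(back), tissueMask(img))
  expect_equal(back@pixelSize, 6.25)
  expect_identical(imageMeta(back)[c("sample_id", "group", "note")],
                   img@meta)
  # generator default: 4000..750 cm-1 at 2 cm-1 spacing, all-true mask
  expect_length(wavenumbers(back), 1626)
  expect_true(all(tissueMask(back)))
  unlink(f)
})

test_that("saveImage refuses to clobber without the overwrite flag", {
  img <- generatePhantom(cleanConfig(rows = 4, cols = 4))@image
  f <- tempfile(fileext = ".h5")
  saveImage(img, f)
  expect_error(saveImage(img, f), "overwrite")
  expect_silent(saveImage(img, f, overwrite = TRUE))
  unlink(f)
})

test_that("malformed containers raise format errors naming the field", {
  f <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  rhdf5::h5write(array(0.1, c(2, 2, 3)), f, "cube")
  rhdf5::h5closeAll()
  expect_error(loadImage(f), "missing dataset '/axis'")
  unlink(f)

  img <- generatePhantom(cleanConfig(rows = 4, cols = 4))@image
  f2 <- tempfile(fileext = ".h5")
  saveImage(img, f2)
  rhdf5::h5delete(f2, "axis")
  rhdf5::h5write(c(1000, 1002, 1004), f2, "axis")  # wrong length
  rhdf5::h5closeAll()
  expect_error(loadImage(f2), "does not match '/axis'")
  unlink(f2)
})

test_that("spectrum tables parse, preserve orientation, and report bad lines", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("# comment", "1000,0.1", "1100,0.2"), f)
  sp <- readSpectrumTable(f)
  expect_length(wavenumbers(sp), 2)
  expect_equal(absorbances(sp), c(0.1, 0.2))

  writeLines(c("1100 0.2", "1000 0.1"), f)  # descending, whitespace-delimited
  sp <- readSpectrumTable(f)
  expect_equal(wavenumbers(sp), c(1100, 1000))
  expect_equal(absorbances(sp), c(0.2, 0.1))

  writeLines(c("1000,0.1", "1200,0.3", "1100,0.2"), f)  # unordered -> sorted
  sp <- readSpectrumTable(f)
  expect_equal(wavenumbers(sp), c(1000, 1100, 1200))
  expect_equal(absorbances(sp), c(0.1, 0.2, 0.3))

  writeLines(c("1655,0.1", "1700,0.2", "1655,0.3"), f)
  expect_error(readSpectrumTable(f), "duplicate wavenumber 1655")
  writeLines(c("1000,0.1", "1100,oops"), f)
  expect_error(readSpectrumTable(f), "line 2")
  writeLines("1000,0.1", f)
  expect_error(readSpectrumTable(f), "at least 2")
  unlink(f)
})

test_that("spectral cropping is inclusive, orientation-preserving and nested-idempotent", {
  axis <- makeAxis(4000, 750, 2)
  sp <- Spectrum(axis, seq_along(axis) * 0.001, "s")
  crop <- cropSpectralRange(sp, 800, 1800)
  expect_length(wavenumbers(crop), 501)  # floor((1800-800)/2) + 1
  expect_true(all(diff(wavenumbers(crop)) < 0))
  expect_equal(range(wavenumbers(crop)), c(800, 1800))

  ident <- cropSpectralRange(sp, min(axis), max(axis))
  expect_identical(absorbances(ident), absorbances(sp))

  again <- cropSpectralRange(crop, 700, 1900)  # wider range: no-op
  expect_identical(absorbances(again), absorbances(crop))

  expect_error(cropSpectralRange(sp, 100, 200), "empty-range")

  img <- generatePhantom(cleanConfig(rows = 4, cols = 4))@image
  ci <- cropSpectralRange(img, 800, 1800)
  expect_equal(dim(absorbances(ci))[3], 501)
})

test_that("linear resampling is exact on shared grids and matches line equations", {
  sp <- Spectrum(c(1000, 1002), c(0, 1), "s")
  expect_equal(absorbances(resampleToAxis(sp, 1001)), 0.5)
  expect_identical(absorbances(resampleToAxis(sp, c(1000, 1002))),
                   c(0, 1))
  # random piecewise-linear spectrum vs direct segment evaluation
  set.seed(5)
  x <- sort(runif(20, 900, 1900))
  y <- rnorm(20)
  sp <- Spectrum(x, y, "pl")
  xt <- sort(runif(50, min(x), max(x)))
  got <- absorbances(resampleToAxis(sp, xt))
  expected <- vapply(xt, function(v) {
    j <- max(which(x <= v)); j <- min(j, length(x) - 1)
    y[j] + (y[j + 1] - y[j]) * (v - x[j]) / (x[j + 1] - x[j])
  }, 0)
  expect_lt(max(abs(got - expected)), 1e-12)
  # linearity in the absorbance argument
  sp2 <- Spectrum(x, 2 * y, "pl2")
  expect_equal(absorbances(resampleToAxis(sp2, xt)), 2 * got)
  expect_error(resampleToAxis(sp, c(800, 1000)), "range error")
})

test_that("label maps render to PNG with the declared colour table", {
  lm <- LabelMap(matrix(c(-1L, 1L, 0L, 1L), 2, 2), k = 2,
                 colorTable = rbind(c(255L, 0L, 0L), c(0L, 255L, 0L)))
  f <- tempfile(fileext = ".png")
  renderLabelMap(lm, f)
  px <- png::readPNG(f)
  expect_equal(px[1, 1, ], c(0, 0, 0))            # background black
  expect_equal(px[1, 2, ], c(1, 0, 0))            # label 0 red
  expect_equal(px[2, 1, ], c(0, 1, 0))            # label 1 green
  expect_equal(px[2, 2, ], c(0, 1, 0))

  allBg <- LabelMap(matrix(-1L, 3, 3), k = 2)
  renderLabelMap(allBg, f)
  expect_true(all(png::readPNG(f) == 0))

  lm10 <- LabelMap(matrix(0:9, 2, 5), k = 10)
  renderLabelMap(lm10, f)
  px <- png::readPNG(f)
  cols <- unique(apply(matrix(px, ncol = 3), 1, paste, collapse = ","))
  expect_length(cols, 10)
  unlink(f)
})
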
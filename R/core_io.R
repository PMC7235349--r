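#' Build a wavenumber axis
#'
#' @param start,end axis endpoints in cm^-1; `start > end` gives the
#'   descending FTIR convention (default 4000 to 750).
#' @param step point spacing in cm^-1 (> 0, default 2).
#' @return numeric axis from `start` towards `end` in steps of `step`.
#' @export
makeAxis <- function(start = 4000, end = 750, step = 2) {
  stopifnot(step > 0, start != end)
  seq(start, end, by = if (start > end) -step else step)
}

#' Save a spectral image to the HDF5 container
#'
#' Layout: datasets `/axis` (float64, cm^-1), `/cube` (float64,
#' rows x cols x n), `/mask` (uint8), root attribute `pixel_size_um`, and a
#' `/meta` group whose string attributes carry the metadata verbatim.
#'
#' @param img a [SpectralImage-class].
#' @param path output file path.
#' @param overwrite logical; refuse to clobber an existing file unless TRUE.
#' @return invisibly, `path`.
#' @seealso [loadImage()]
#' @export
saveImage <- function(img, path, overwrite = FALSE) {
  stopifnot(is(img, "SpectralImage"))
  validObject(img)
  if (file.exists(path)) {
    if (!overwrite) stop("file exists and overwrite = FALSE: ", path)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(img@axis, path, "axis")
  suppressMessages(rhdf5::h5write(img@cube, path, "cube"))
  m <- img@mask
  storage.mode(m) <- "integer"
  rhdf5::h5createDataset(path, "mask", dims = dim(m), H5type = "H5T_STD_U8LE")
  rhdf5::h5write(m, path, "mask")
  rhdf5::h5createGroup(path, "meta")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(img@pixelSize, fid, "pixel_size_um")
  gid <- rhdf5::H5Gopen(fid, "meta")
  for (key in names(img@meta))
    rhdf5::h5writeAttribute(as.character(img@meta[[key]]), gid, key)
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Load a spectral image from the HDF5 container
#'
#' Round-trips bit-exactly with [saveImage()] for the axis and cube.
#'
#' @param path path to a container written by [saveImage()].
#' @return a [SpectralImage-class].
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  have <- ls$name[ls$group == "/"]
  for (ds in c("axis", "cube", "mask"))
    if (!ds %in% have)
      stop("format error: missing dataset '/", ds, "' in ", path)
  axis <- as.numeric(rhdf5::h5read(path, "axis"))
  cube <- rhdf5::h5read(path, "cube")
  maskInt <- rhdf5::h5read(path, "mask")
  ok <- validAxis(axis)
  if (!isTRUE(ok)) stop("format error in '/axis': ", ok)
  if (length(dim(cube)) != 3 || dim(cube)[3] != length(axis))
    stop("format error: '/cube' third dimension (", paste(dim(cube),
         collapse = "x"), ") does not match '/axis' length ", length(axis))
  mask <- matrix(as.logical(maskInt), nrow = dim(cube)[1])
  rootAttr <- rhdf5::h5readAttributes(path, "/")
  px <- rootAttr[["pixel_size_um"]]
  if (is.null(px)) stop("format error: missing attribute 'pixel_size_um'")
  meta <- list()
  if ("meta" %in% have) {
    ma <- rhdf5::h5readAttributes(path, "meta")
    meta <- lapply(ma, function(v) as.character(v)[1])
  }
  SpectralImage(axis = axis, cube = cube, pixelSize = as.numeric(px),
                mask = mask, meta = meta)
}

#' Read a reference spectrum from two-column delimited text
#'
#' Columns are wavenumber (cm^-1) and absorbance (AU), separated by commas or
#' whitespace; lines starting with '#' are comments. Rows already in strictly
#' ascending or descending order keep their orientation; unordered rows are
#' sorted ascending with the pairing preserved.
#'
#' @param path file path.
#' @param name spectrum name; defaults to the file stem.
#' @return a [Spectrum-class].
#' @export
readSpectrumTable <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  rows <- trimws(lines[keep])
  if (length(rows) < 2)
    stop("parse error: need at least 2 data rows, found ", length(rows))
  parts <- strsplit(rows, "[,[:space:]]+")
  w <- numeric(length(rows)); a <- numeric(length(rows))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2)
      stop("parse error at line ", lineNo[i], ": expected two columns")
    v <- suppressWarnings(as.numeric(p[1:2]))
    if (any(is.na(v)))
      stop("parse error at line ", lineNo[i], ": non-numeric cell")
    w[i] <- v[1]; a[i] <- v[2]
  }
  dup <- which(duplicated(w))
  if (length(dup))
    stop("parse error at line ", lineNo[dup[1]], ": duplicate wavenumber ",
         w[dup[1]])
  if (!isStrictlyMonotonic(w)) {
    o <- order(w)
    w <- w[o]; a <- a[o]
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  Spectrum(axis = w, absorbance = a, name = name)
}

#' Write a spectrum as two-column delimited text
#'
#' @param spec a [Spectrum-class].
#' @param path output path.
#' @param digits significant digits (default 10).
#' @return invisibly, `path`.
#' @export
writeSpectrumTable <- function(spec, path, digits = 10) {
  stopifnot(is(spec, "Spectrum"))
  fmt <- paste0("%.", digits, "g")
  writeLines(c(paste0("# ", spec@name),
               paste(sprintf(fmt, spec@axis), sprintf(fmt, spec@absorbance),
                     sep = ",")), path)
  invisible(path)
}

cropIndex <- function(axis, lo, hi) {
  if (!(lo < hi)) stop("require lo < hi")
  idx <- which(axis >= lo & axis <= hi)
  if (length(idx) == 0)
    stop("empty-range: no channels in [", lo, ", ", hi, "] cm-1")
  idx
}

#' @rdname cropSpectralRange
setMethod("cropSpectralRange", "Spectrum", function(x, lo, hi) {
  idx <- cropIndex(x@axis, lo, hi)
  Spectrum(x@axis[idx], x@absorbance[idx], x@name)
})

#' @rdname cropSpectralRange
setMethod("cropSpectralRange", "SpectralImage", function(x, lo, hi) {
  idx <- cropIndex(x@axis, lo, hi)
  SpectralImage(axis = x@axis[idx], cube = x@cube[, , idx, drop = FALSE],
                pixelSize = x@pixelSize, mask = x@mask, meta = x@meta)
})

#' Resample a spectrum onto a target wavenumber axis
#'
#' Piecewise-linear interpolation between bracketing points; exact at shared
#' grid points. Extrapolation is refused.
#'
#' @param spec a [Spectrum-class].
#' @param target numeric target axis, or a [Spectrum-class] whose axis is used.
#' @return a [Spectrum-class] on the target axis.
#' @export
resampleToAxis <- function(spec, target) {
  stopifnot(is(spec, "Spectrum"))
  if (is(target, "Spectrum")) target <- target@axis
  target <- as.numeric(target)
  rng <- range(spec@axis)
  if (min(target) < rng[1] || max(target) > rng[2])
    stop("range error: target axis [", min(target), ", ", max(target),
         "] extends beyond spectrum range [", rng[1], ", ", rng[2], "]")
  o <- order(spec@axis) # approx with ties = "ordered" needs ascending x
  y <- stats::approx(spec@axis[o], spec@absorbance[o], xout = target,
                     method = "linear", ties = "ordered")$y
  Spectrum(target, y, spec@name)
}

# Precompute linear-interpolation weights from one axis onto another; applied
# to pixel matrices so image resampling is a single matrix product.
interpWeights <- function(from, to) {
  rng <- range(from)
  if (min(to) < rng[1] || max(to) > rng[2])
    stop("range error: target axis extends beyond source axis")
  o <- order(from)
  fs <- from[o]
  j <- findInterval(to, fs, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), length(fs) - 1L)
  wR <- (to - fs[j]) / (fs[j + 1L] - fs[j])
  list(i1 = o[j], i2 = o[j + 1L], w1 = 1 - wR, w2 = wR)
}

#' Render a label map as an 8-bit RGB PNG
#'
#' Background pixels (-1) render black; label `j` renders row `j + 1` of the
#' colour table.
#'
#' @param lm a [LabelMap-class].
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
renderLabelMap <- function(lm, path) {
  stopifnot(is(lm, "LabelMap"))
  validObject(lm)
  l <- lm@labels
  img <- array(0, dim = c(nrow(l), ncol(l), 3))
  for (j in seq_len(lm@k) - 1L) {
    sel <- l == j
    if (!any(sel)) next
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- lm@colorTable[j + 1L, ch] / 255
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, target = path)
  invisible(path)
}
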
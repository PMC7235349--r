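#' @import methods
NULL

#' Tissue classes modelled by the skin phantoms
#'
#' Fixed class order used by ground-truth label maps: epidermis, dermis,
#' hypodermis, muscle, subcutaneous fat, hair bulb. Row 0 of a phantom is the
#' top of the section (epidermis side).
#' @export
TISSUE_CLASSES <- c("epidermis", "dermis", "hypodermis", "muscle",
                    "subcutaneous_fat", "hair_bulb")

validAxis <- function(axis, what = "axis", minLen = 2) {
  if (length(axis) < minLen)
    return(sprintf("%s must have length >= %d", what, minLen))
  if (!all(is.finite(axis))) return(sprintf("%s has non-finite values", what))
  if (any(axis <= 0)) return(sprintf("%s must be positive wavenumbers", what))
  if (length(axis) >= 2 && !isStrictlyMonotonic(axis))
    return(sprintf("%s must be strictly monotonic", what))
  TRUE
}

#' Single infrared spectrum
#'
#' A wavenumber axis (cm^-1, strictly monotonic, either orientation) paired
#' with an absorbance vector (AU) and a name.
#'
#' @slot axis numeric wavenumber axis in cm^-1.
#' @slot absorbance numeric absorbance values (AU), same length as `axis`.
#' @slot name character(1) identifier.
#' @export
setClass("Spectrum",
  representation(axis = "numeric", absorbance = "numeric", name = "character"),
  validity = function(object) {
    # length 1 permitted: resampling onto a single query point is legal
    ok <- validAxis(object@axis, minLen = 1)
    if (!isTRUE(ok)) return(ok)
    if (length(object@absorbance) != length(object@axis))
      return("absorbance and axis lengths differ")
    if (!all(is.finite(object@absorbance)))
      return("absorbance has non-finite values")
    TRUE
  })

#' Construct a Spectrum
#' @param axis numeric wavenumber axis (cm^-1).
#' @param absorbance numeric absorbance vector (AU).
#' @param name character(1) name.
#' @return a [Spectrum-class] object.
#' @export
Spectrum <- function(axis, absorbance, name = "spectrum") {
  new("Spectrum", axis = as.numeric(axis), absorbance = as.numeric(absorbance),
      name = as.character(name)[1])
}

#' Hyperspectral absorbance image
#'
#' The central container of the pipeline: a `rows x cols x n_wavenumbers`
#' absorbance cube with its wavenumber axis, pixel size, tissue mask and
#' free-form string metadata.
#'
#' @slot axis numeric wavenumber axis (cm^-1), strictly monotonic.
#' @slot cube numeric 3-D array, third dimension indexed by `axis`.
#' @slot pixelSize numeric(1), pixel edge in micrometres.
#' @slot mask logical matrix, TRUE = tissue pixel.
#' @slot meta named list of character scalars (sample id, group, provenance).
#' @export
setClass("SpectralImage",
  representation(axis = "numeric", cube = "array", pixelSize = "numeric",
                 mask = "matrix", meta = "list"),
  validity = function(object) {
    ok <- validAxis(object@axis)
    if (!isTRUE(ok)) return(ok)
    d <- dim(object@cube)
    if (length(d) != 3) return("cube must be a 3-D array")
    if (d[3] != length(object@axis))
      return("cube third dimension does not match axis length")
    if (!identical(dim(object@mask), d[1:2]))
      return("mask shape does not match cube spatial dimensions")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
      return("pixelSize must be a positive scalar")
    TRUE
  })

#' Construct a SpectralImage
#' @param axis numeric wavenumber axis (cm^-1).
#' @param cube numeric array `rows x cols x length(axis)` (AU).
#' @param pixelSize pixel edge in micrometres (default 6.25).
#' @param mask logical matrix; defaults to all-tissue.
#' @param meta named list of character metadata.
#' @return a [SpectralImage-class] object.
#' @export
SpectralImage <- function(axis, cube, pixelSize = 6.25, mask = NULL,
                          meta = list()) {
  if (is.null(mask))
    mask <- matrix(TRUE, nrow = dim(cube)[1], ncol = dim(cube)[2])
  new("SpectralImage", axis = as.numeric(axis), cube = cube,
      pixelSize = as.numeric(pixelSize), mask = mask,
      meta = lapply(meta, as.character))
}

#' Integer label map with colour table
#'
#' Cluster (or ground-truth tissue) labels per pixel: -1 marks background or
#' masked pixels, 0..k-1 are class ids rendered with `colorTable`.
#'
#' @slot labels integer matrix of labels in \{-1, 0..k-1\}.
#' @slot k integer(1) number of classes.
#' @slot colorTable integer matrix `k x 3` of RGB triples (0..255).
#' @slot classNames character vector of length `k` (or empty) naming classes.
#' @export
setClass("LabelMap",
  representation(labels = "matrix", k = "integer", colorTable = "matrix",
                 classNames = "character"),
  validity = function(object) {
    if (object@k < 1) return("k must be positive")
    l <- object@labels
    if (!is.integer(l)) return("labels must be integer")
    if (any(l < -1L | l >= object@k)) return("labels outside {-1, 0..k-1}")
    if (nrow(object@colorTable) != object@k || ncol(object@colorTable) != 3)
      return("colorTable must be k x 3")
    if (length(object@classNames) > 0 && length(object@classNames) != object@k)
      return("classNames must be empty or length k")
    TRUE
  })

#' Construct a LabelMap
#' @param labels integer matrix (-1 = background, 0..k-1 = classes).
#' @param k number of classes; defaults to `max(labels) + 1`.
#' @param colorTable `k x 3` RGB matrix; defaults to [clusterPalette()].
#' @param classNames optional class names (length `k`).
#' @return a [LabelMap-class] object.
#' @export
LabelMap <- function(labels, k = NULL, colorTable = NULL,
                     classNames = character()) {
  storage.mode(labels) <- "integer"
  if (is.null(k)) k <- max(labels) + 1L
  k <- as.integer(k)
  if (is.null(colorTable)) colorTable <- clusterPalette(k)
  new("LabelMap", labels = labels, k = k, colorTable = colorTable,
      classNames = as.character(classNames))
}

#' EMSC model basis for digital dewaxing
#'
#' Columns of the least-squares design: the tissue target spectrum `m`, the
#' paraffin interference spectra (mean + principal-component loadings) and
#' polynomial baseline terms on the axis rescaled to [-1, 1].
#'
#' @slot target [Spectrum-class] tissue reference `m`.
#' @slot interference list of [Spectrum-class] interference components.
#' @slot polyOrder integer(1) polynomial baseline order (>= 0).
#' @slot axis numeric common wavenumber axis.
#' @slot design numeric design matrix `[m | interference | polynomials]`.
#' @export
setClass("EMSCBasis",
  representation(target = "Spectrum", interference = "list",
                 polyOrder = "integer", axis = "numeric", design = "matrix"),
  validity = function(object) {
    ok <- validAxis(object@axis)
    if (!isTRUE(ok)) return(ok)
    if (object@polyOrder < 0) return("polyOrder must be >= 0")
    if (!identical(object@target@axis, object@axis))
      return("target axis differs from basis axis")
    for (s in object@interference)
      if (!identical(s@axis, object@axis))
        return("interference spectrum axis differs from basis axis")
    if (nrow(object@design) != length(object@axis))
      return("design row count does not match axis")
    TRUE
  })

#' Per-spectrum EMSC fit coefficients
#'
#' @slot c numeric(1) multiplicative scale (section thickness proxy).
#' @slot b numeric interference coefficients (paraffin contribution).
#' @slot d numeric polynomial baseline coefficients (length polyOrder + 1).
#' @slot residualRms numeric(1) root-mean-square of the fit residual (AU).
#' @export
setClass("EMSCFit",
  representation(c = "numeric", b = "numeric", d = "numeric",
                 residualRms = "numeric"))

#' Pixel rejection rule applied during dewaxing
#'
#' Pixels whose fitted scale |c| falls below `cMin` (blank paraffin, holes) or
#' whose residual RMS exceeds `residualMax` (outliers) are masked out.
#'
#' @slot cMin numeric(1) minimum |c| (default 0.2).
#' @slot residualMax numeric(1) maximum residual RMS; `Inf` disables.
#' @export
setClass("MaskRule",
  representation(cMin = "numeric", residualMax = "numeric"),
  validity = function(object) {
    if (object@cMin <= 0) return("cMin must be > 0")
    TRUE
  })

#' Construct a MaskRule
#' @param cMin minimum fitted |c| for a pixel to count as tissue.
#' @param residualMax maximum residual RMS (AU); `Inf` to disable.
#' @return a [MaskRule-class] object.
#' @export
maskRule <- function(cMin = 0.2, residualMax = Inf) {
  new("MaskRule", cMin = as.numeric(cMin), residualMax = as.numeric(residualMax))
}

#' Pooled K-means model shared across images
#'
#' @slot k integer(1) number of clusters.
#' @slot centroids numeric matrix `k x n_wavenumbers`.
#' @slot axis numeric processed wavenumber axis (may be empty for raw fits).
#' @slot inertia numeric(1) total within-cluster sum of squares.
#' @slot seed integer(1) seed used for the restarts.
#' @slot nInit integer(1) number of k-means++ restarts.
#' @slot colorTable integer matrix `k x 3` fixed cluster colours.
#' @export
setClass("ClusterModel",
  representation(k = "integer", centroids = "matrix", axis = "numeric",
                 inertia = "numeric", seed = "integer", nInit = "integer",
                 colorTable = "matrix"),
  validity = function(object) {
    if (nrow(object@centroids) != object@k) return("centroid count != k")
    if (object@inertia < 0) return("inertia must be >= 0")
    if (anyDuplicated(object@centroids) > 0)
      return("centroids must be pairwise distinct")
    TRUE
  })

#' Pixel-wise correlation map against a reference spectrum
#'
#' @slot rRaw numeric matrix of Pearson coefficients in [-1, 1]; masked or
#'   constant pixels are NA.
#' @slot rDisplay numeric matrix clipped to [0, 1] for display.
#' @slot range numeric(2) wavenumber range (lo, hi) used.
#' @slot mode character(1) label of the spectra correlated (e.g. "raw",
#'   "dewaxed").
#' @export
setClass("CorrelationMap",
  representation(rRaw = "matrix", rDisplay = "matrix", range = "numeric",
                 mode = "character"),
  validity = function(object) {
    if (!identical(dim(object@rRaw), dim(object@rDisplay)))
      return("rRaw and rDisplay shapes differ")
    ok <- object@rDisplay[!is.na(object@rDisplay)]
    if (length(ok) && (any(ok < 0) || any(ok > 1)))
      return("rDisplay outside [0, 1]")
    TRUE
  })

#' Spectral band of a model endmember
#'
#' @slot center numeric(1) band centre (cm^-1).
#' @slot fwhm numeric(1) full width at half maximum (cm^-1), > 0.
#' @slot amplitude numeric(1) peak amplitude (AU).
#' @slot shape character(1), "gaussian" or "lorentzian".
#' @export
setClass("Band",
  representation(center = "numeric", fwhm = "numeric", amplitude = "numeric",
                 shape = "character"),
  validity = function(object) {
    if (object@fwhm <= 0) return("fwhm must be > 0")
    if (!object@shape %in% c("gaussian", "lorentzian"))
      return("shape must be gaussian or lorentzian")
    TRUE
  })

#' Construct a Band
#' @param center band centre (cm^-1).
#' @param fwhm full width at half maximum (cm^-1).
#' @param amplitude peak amplitude (AU).
#' @param shape "gaussian" (default) or "lorentzian".
#' @return a [Band-class] object.
#' @export
band <- function(center, fwhm, amplitude, shape = "gaussian") {
  new("Band", center = as.numeric(center), fwhm = as.numeric(fwhm),
      amplitude = as.numeric(amplitude), shape = shape)
}

#' Band model of a tissue (or paraffin) endmember spectrum
#'
#' @slot name character(1) endmember name.
#' @slot bands list of [Band-class] objects (at least one).
#' @slot offset numeric(1) constant absorbance offset (AU).
#' @export
setClass("TissueEndmember",
  representation(name = "character", bands = "list", offset = "numeric"),
  validity = function(object) {
    if (length(object@bands) < 1) return("endmember needs at least one band")
    if (!all(vapply(object@bands, is, TRUE, "Band")))
      return("bands must all be Band objects")
    TRUE
  })

#' Construct a TissueEndmember
#' @param name endmember name.
#' @param bands list of [band()] objects.
#' @param offset constant absorbance offset (AU).
#' @return a [TissueEndmember-class] object.
#' @export
tissueEndmember <- function(name, bands, offset = 0) {
  new("TissueEndmember", name = as.character(name), bands = bands,
      offset = as.numeric(offset))
}

#' Configuration of a synthetic skin phantom
#'
#' Defaults reflect the emulated acquisition: 6.25 um pixels, 4000-750 cm^-1
#' at 2 cm^-1 spacing, layered ventral-skin anatomy, moderate paraffin load,
#' quadratic baseline drift, ~10% section-thickness variation and i.i.d.
#' detector noise.
#'
#' @slot rows,cols integer image size in pixels.
#' @slot pixelSize numeric pixel edge (um).
#' @slot axisStart,axisEnd,axisStep numeric axis definition (cm^-1).
#' @slot group character "WT" or "KO".
#' @slot dermisThicknessRatio numeric KO:WT dermis thickness ratio.
#' @slot layerFractionsWT named numeric WT layer height fractions (sum 1).
#' @slot nHairBulbs integer number of elliptical hair bulbs in the dermis.
#' @slot paraffinAmplitudeMean,paraffinAmplitudeSd numeric paraffin scale
#'   distribution (truncated at 0).
#' @slot baselineOrder integer polynomial baseline order.
#' @slot baselineAmplitude numeric scale of random baseline coefficients (AU).
#' @slot thicknessMean,thicknessSd numeric section-thickness scale
#'   distribution (truncated > 0).
#' @slot noiseSd numeric i.i.d. noise standard deviation (AU).
#' @slot seed integer phantom seed.
#' @slot endmembers list of [TissueEndmember-class]; empty = package defaults.
#' @export
setClass("PhantomConfig",
  representation(rows = "integer", cols = "integer", pixelSize = "numeric",
                 axisStart = "numeric", axisEnd = "numeric",
                 axisStep = "numeric", group = "character",
                 dermisThicknessRatio = "numeric",
                 layerFractionsWT = "numeric", nHairBulbs = "integer",
                 paraffinAmplitudeMean = "numeric",
                 paraffinAmplitudeSd = "numeric", baselineOrder = "integer",
                 baselineAmplitude = "numeric", thicknessMean = "numeric",
                 thicknessSd = "numeric", noiseSd = "numeric",
                 seed = "integer", endmembers = "list"),
  validity = function(object) {
    if (object@rows < 4 || object@cols < 1)
      return("rows/cols too small for a layered phantom")
    if (object@axisStep <= 0) return("axisStep must be > 0")
    if (!object@group %in% c("WT", "KO")) return("group must be WT or KO")
    if (object@dermisThicknessRatio <= 0)
      return("dermisThicknessRatio must be > 0")
    f <- object@layerFractionsWT
    need <- TISSUE_CLASSES[1:5]
    if (!identical(sort(names(f)), sort(need)))
      return("layerFractionsWT must name exactly the five layers")
    if (abs(sum(f) - 1) > 1e-8) return("WT layer fractions must sum to 1")
    if (any(f <= 0)) return("layer fractions must be positive")
    if (object@nHairBulbs < 0) return("nHairBulbs must be >= 0")
    sds <- c(object@paraffinAmplitudeSd, object@thicknessSd, object@noiseSd,
             object@baselineAmplitude)
    if (any(sds < 0)) return("spread parameters must be >= 0")
    if (object@thicknessMean <= 0) return("thicknessMean must be > 0")
    if (object@baselineOrder < 0) return("baselineOrder must be >= 0")
    TRUE
  })

#' Construct a PhantomConfig
#'
#' @param rows,cols image size in pixels (default 64 x 64).
#' @param pixelSize pixel edge in micrometres (default 6.25).
#' @param axisStart,axisEnd,axisStep wavenumber axis (default 4000 to 750,
#'   2 cm^-1 point spacing).
#' @param group "WT" or "KO".
#' @param dermisThicknessRatio KO:WT dermis thickness ratio (default 2).
#' @param layerFractionsWT named WT layer height fractions summing to 1.
#' @param nHairBulbs number of hair bulbs carved into the dermis (default 3).
#' @param paraffinAmplitudeMean,paraffinAmplitudeSd per-pixel paraffin scale,
#'   Normal truncated at 0 (defaults 0.3, 0.1).
#' @param baselineOrder polynomial baseline order (default 2).
#' @param baselineAmplitude sd of random baseline coefficients in AU
#'   (default 0.02).
#' @param thicknessMean,thicknessSd per-pixel thickness scale, Normal
#'   truncated > 0 (defaults 1, 0.1).
#' @param noiseSd i.i.d. noise sd in AU (default 0.005).
#' @param seed integer phantom seed.
#' @param endmembers optional list of [TissueEndmember-class] overriding
#'   [defaultEndmembers()].
#' @return a [PhantomConfig-class] object.
#' @export
phantomConfig <- function(rows = 64, cols = 64, pixelSize = 6.25,
                          axisStart = 4000, axisEnd = 750, axisStep = 2,
                          group = "WT", dermisThicknessRatio = 2,
                          layerFractionsWT = c(epidermis = 0.1, dermis = 0.3,
                                               hypodermis = 0.2, muscle = 0.2,
                                               subcutaneous_fat = 0.2),
                          nHairBulbs = 3, paraffinAmplitudeMean = 0.3,
                          paraffinAmplitudeSd = 0.1, baselineOrder = 2,
                          baselineAmplitude = 0.02, thicknessMean = 1,
                          thicknessSd = 0.1, noiseSd = 0.005, seed = 1,
                          endmembers = list()) {
  new("PhantomConfig", rows = as.integer(rows), cols = as.integer(cols),
      pixelSize = as.numeric(pixelSize), axisStart = as.numeric(axisStart),
      axisEnd = as.numeric(axisEnd), axisStep = as.numeric(axisStep),
      group = group, dermisThicknessRatio = as.numeric(dermisThicknessRatio),
      layerFractionsWT = layerFractionsWT, nHairBulbs = as.integer(nHairBulbs),
      paraffinAmplitudeMean = as.numeric(paraffinAmplitudeMean),
      paraffinAmplitudeSd = as.numeric(paraffinAmplitudeSd),
      baselineOrder = as.integer(baselineOrder),
      baselineAmplitude = as.numeric(baselineAmplitude),
      thicknessMean = as.numeric(thicknessMean),
      thicknessSd = as.numeric(thicknessSd), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed), endmembers = endmembers)
}

#' Synthetic phantom with ground truth
#'
#' @slot image the generated [SpectralImage-class].
#' @slot truth ground-truth tissue [LabelMap-class].
#' @slot trueThickness numeric matrix of per-pixel thickness scales.
#' @slot trueParaffin numeric matrix of per-pixel paraffin amplitudes.
#' @slot config the generating [PhantomConfig-class].
#' @export
setClass("PhantomImage",
  representation(image = "SpectralImage", truth = "LabelMap",
                 trueThickness = "matrix", trueParaffin = "matrix",
                 config = "PhantomConfig"))

#' @export
setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s': %d points, %g..%g cm-1\n", object@name,
              length(object@axis), object@axis[1],
              object@axis[length(object@axis)]))
})

#' @export
setMethod("show", "SpectralImage", function(object) {
  d <- dim(object@cube)
  cat(sprintf(
    "SpectralImage: %d x %d pixels (%.2f um), %d channels %g..%g cm-1, %d tissue pixels\n",
    d[1], d[2], object@pixelSize, d[3], object@axis[1], object@axis[d[3]],
    sum(object@mask)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(object@meta), sep = "=",
                         collapse = ", "), "\n")
})

#' @export
setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap: %d x %d, k = %d, %d background pixels\n",
              nrow(object@labels), ncol(object@labels), object@k,
              sum(object@labels == -1L)))
})

#' @export
setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, %d channels, inertia = %.6g (seed %d, %d restarts)\n",
              object@k, ncol(object@centroids), object@inertia, object@seed,
              object@nInit))
})

#' @export
setMethod("show", "CorrelationMap", function(object) {
  cat(sprintf("CorrelationMap (%s): %d x %d, range %g..%g cm-1\n",
              object@mode, nrow(object@rRaw), ncol(object@rRaw),
              object@range[1], object@range[2]))
})

#' @export
setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %d x %d px, group %s, dermis ratio %.2f, seed %d\n",
    object@rows, object@cols, object@group, object@dermisThicknessRatio,
    object@seed))
})

#' @export
setMethod("show", "EMSCBasis", function(object) {
  cat(sprintf(
    "EMSCBasis: target '%s', %d interference spectra, poly order %d, %d channels\n",
    object@target@name, length(object@interference), object@polyOrder,
    length(object@axis)))
})
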
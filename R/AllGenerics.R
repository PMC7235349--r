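#' Wavenumber axis accessor
#' @param x a Spectrum, SpectralImage, EMSCBasis or ClusterModel.
#' @return numeric wavenumber axis (cm^-1).
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname wavenumbers
setMethod("wavenumbers", "Spectrum", function(x) x@axis)
#' @rdname wavenumbers
setMethod("wavenumbers", "SpectralImage", function(x) x@axis)
#' @rdname wavenumbers
setMethod("wavenumbers", "EMSCBasis", function(x) x@axis)
#' @rdname wavenumbers
setMethod("wavenumbers", "ClusterModel", function(x) x@axis)

#' Absorbance accessor
#' @param x a Spectrum (vector) or SpectralImage (3-D array).
#' @return absorbance values (AU).
#' @export
setGeneric("absorbances", function(x) standardGeneric("absorbances"))

#' @rdname absorbances
setMethod("absorbances", "Spectrum", function(x) x@absorbance)
#' @rdname absorbances
setMethod("absorbances", "SpectralImage", function(x) x@cube)

#' Tissue mask accessor
#' @param x a SpectralImage.
#' @return logical matrix (TRUE = tissue).
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))

#' @rdname tissueMask
setMethod("tissueMask", "SpectralImage", function(x) x@mask)

#' Label matrix accessor
#' @param x a LabelMap.
#' @return integer matrix of labels (-1 = background).
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname labelMatrix
setMethod("labelMatrix", "LabelMap", function(x) x@labels)

#' Centroid matrix accessor
#' @param x a ClusterModel.
#' @return numeric matrix `k x n_wavenumbers`.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname centroids
setMethod("centroids", "ClusterModel", function(x) x@centroids)

#' Image metadata accessor
#' @param x a SpectralImage.
#' @return named list of character metadata.
#' @export
setGeneric("imageMeta", function(x) standardGeneric("imageMeta"))

#' @rdname imageMeta
setMethod("imageMeta", "SpectralImage", function(x) x@meta)

#' Restrict to a wavenumber range
#'
#' Keeps exactly the channels with `lo <= wavenumber <= hi` (closed interval,
#' both ends included), preserving the axis orientation.
#'
#' @param x a Spectrum or SpectralImage.
#' @param lo,hi range bounds in cm^-1, `lo < hi`.
#' @return an object of the same class restricted to the range.
#' @export
setGeneric("cropSpectralRange",
           function(x, lo, hi) standardGeneric("cropSpectralRange"))
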
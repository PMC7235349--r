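#' Evaluate a band-model endmember on a wavenumber axis
#'
#' Absorbance(v) = offset + sum over bands of amplitude * profile(v), with
#' Gaussian profile exp(-4 ln2 (v - c)^2 / fwhm^2) or Lorentzian profile
#' 1 / (1 + 4 (v - c)^2 / fwhm^2); each band peaks at `offset + amplitude`
#' when bands do not overlap.
#'
#' @param em a [TissueEndmember-class].
#' @param axis numeric wavenumber axis (cm^-1).
#' @return a [Spectrum-class] named after the endmember.
#' @export
buildEndmember <- function(em, axis) {
  stopifnot(is(em, "TissueEndmember"))
  ok <- validAxis(axis)
  if (!isTRUE(ok)) stop(ok)
  y <- rep(em@offset, length(axis))
  for (b in em@bands) {
    u <- (axis - b@center) / b@fwhm
    prof <- switch(b@shape,
                   gaussian = exp(-4 * log(2) * u^2),
                   lorentzian = 1 / (1 + 4 * u^2))
    y <- y + b@amplitude * prof
  }
  Spectrum(axis, y, em@name)
}

#' Default tissue endmember band models
#'
#' Generic protein/lipid mid-infrared assignments: dermis carries the type I
#' collagen signature (amide A ~3300, amide I ~1660, amide II ~1550 and the
#' amide III triplet at 1330/1280/1204 cm^-1); epidermis is keratin-like
#' protein with a small ester shoulder; hypodermis and subcutaneous fat are
#' lipid-dominated (ester C=O 1745, CH2 1465) with decreasing protein
#' content; muscle is protein with a higher amide II/I ratio; hair bulbs add
#' a broad carbohydrate-region band near 1040 cm^-1.
#'
#' @return named list of six [TissueEndmember-class] objects in
#'   [TISSUE_CLASSES] order.
#' @export
defaultEndmembers <- function() {
  ems <- list(
    tissueEndmember("epidermis", list(
      band(3300, 150, 0.50), band(2960, 30, 0.15),
      band(1745, 30, 0.08), band(1655, 50, 0.90), band(1545, 50, 0.42),
      band(1452, 30, 0.12), band(1240, 60, 0.10), band(1080, 60, 0.08)),
      offset = 0.02),
    tissueEndmember("dermis", list(
      band(3300, 150, 0.60), band(2940, 30, 0.10),
      band(1660, 50, 1.00), band(1550, 50, 0.55),
      band(1450, 30, 0.10), band(1330, 25, 0.18), band(1280, 25, 0.15),
      band(1204, 25, 0.12), band(1080, 60, 0.06)),
      offset = 0.02),
    tissueEndmember("hypodermis", list(
      band(2920, 30, 0.90), band(2850, 30, 0.60),
      band(1745, 30, 0.80), band(1650, 50, 0.25), band(1545, 50, 0.12),
      band(1465, 25, 0.45), band(1170, 40, 0.30)),
      offset = 0.02),
    tissueEndmember("muscle", list(
      band(3290, 150, 0.55), band(2955, 30, 0.12),
      band(1655, 45, 1.00), band(1545, 45, 0.75),
      band(1452, 30, 0.14), band(1240, 50, 0.08), band(1030, 50, 0.15)),
      offset = 0.02),
    tissueEndmember("subcutaneous_fat", list(
      band(2920, 30, 1.10), band(2850, 30, 0.70),
      band(1745, 30, 1.00), band(1650, 50, 0.15), band(1545, 50, 0.08),
      band(1465, 25, 0.55), band(1170, 40, 0.40)),
      offset = 0.02),
    tissueEndmember("hair_bulb", list(
      band(3300, 150, 0.50), band(2960, 30, 0.12),
      band(1652, 50, 0.80), band(1540, 50, 0.50),
      band(1452, 30, 0.10), band(1040, 80, 0.35)),
      offset = 0.02))
  names(ems) <- vapply(ems, function(e) e@name, "")
  ems[TISSUE_CLASSES]
}

#' Paraffin endmember band model
#'
#' Standard alkane assignments: CH2 scissoring doublet at 1462/1472 cm^-1 and
#' the CH3 bend at 1378 cm^-1 inside the processed fingerprint range, plus
#' the strong CH stretches at 2920/2850 cm^-1 outside it.
#'
#' @return a [TissueEndmember-class] named "paraffin".
#' @export
paraffinEndmember <- function() {
  tissueEndmember("paraffin", list(
    band(2920, 25, 1.20), band(2850, 25, 0.80),
    band(1472, 10, 0.70), band(1462, 10, 0.90), band(1378, 15, 0.45)),
    offset = 0)
}

# Endmember spectra as a classes x channels matrix, in TISSUE_CLASSES order.
endmemberMatrix <- function(endmembers, axis) {
  t(vapply(endmembers, function(em) buildEndmember(em, axis)@absorbance,
           numeric(length(axis))))
}
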
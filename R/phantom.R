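# Truncated-normal draws by rejection; deterministic under withSeed.
truncNorm <- function(n, mean, sd, lower = 0, inclusive = FALSE) {
  if (sd == 0) {
    bad <- if (inclusive) mean < lower else mean <= lower
    if (bad) stop("degenerate truncated normal: mean at or below bound")
    return(rep(mean, n))
  }
  x <- stats::rnorm(n, mean, sd)
  repeat {
    bad <- if (inclusive) x < lower else x <= lower
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Row counts per layer for a config, after applying the KO dermis ratio.
layerRowCounts <- function(cfg) {
  f <- cfg@layerFractionsWT[TISSUE_CLASSES[1:5]]
  if (cfg@group == "KO") {
    fd <- f[["dermis"]] * cfg@dermisThicknessRatio
    if (fd >= 1)
      stop("configuration error: KO dermis fraction ", signif(fd, 3),
           " does not fit in the image; reduce the WT dermis fraction or the ratio")
    scale <- (1 - fd) / (1 - f[["dermis"]])
    f <- f * scale
    f[["dermis"]] <- fd
  }
  counts <- apportionRows(f, cfg@rows)
  names(counts) <- names(f)
  counts
}

#' Generate the layered ground-truth layout of a skin phantom
#'
#' Horizontal layers top to bottom in the order epidermis, dermis,
#' hypodermis, muscle, subcutaneous fat, with row counts apportioned from the
#' layer fractions (largest-remainder rounding). For `group = "KO"` the
#' dermis fraction is multiplied by the dermis thickness ratio and the other
#' layers are rescaled proportionally so the image height is unchanged.
#' `nHairBulbs` non-overlapping elliptical hair-bulb regions are placed
#' inside the dermis, deterministically given the config seed.
#'
#' @param cfg a [PhantomConfig-class].
#' @return a ground-truth [LabelMap-class] with `k = 6` and class names
#'   [TISSUE_CLASSES].
#' @export
generateLayout <- function(cfg) {
  stopifnot(is(cfg, "PhantomConfig"))
  validObject(cfg)
  counts <- layerRowCounts(cfg)
  rowClass <- rep.int(0:4, counts)
  labels <- matrix(rowClass, nrow = cfg@rows, ncol = cfg@cols)
  if (cfg@nHairBulbs > 0) {
    dTop <- sum(counts[1]) + 1L
    dBot <- dTop + counts[2] - 1L
    dRows <- counts[[2]]
    ry <- max(2L, dRows %/% 5L)
    rx <- max(3L, as.integer(round(1.6 * ry)))
    if (dRows < 2L * ry + 1L || cfg@cols < 2L * rx + 1L)
      stop("configuration error: dermis too thin (or image too narrow) to ",
           "place hair bulbs")
    withSeed(deriveSeed(cfg@seed, 1L), {
      occupied <- matrix(FALSE, cfg@rows, cfg@cols)
      placed <- 0L
      attempts <- 0L
      while (placed < cfg@nHairBulbs) {
        attempts <- attempts + 1L
        if (attempts > 500L)
          stop("configuration error: could not place ", cfg@nHairBulbs,
               " non-overlapping hair bulbs in the dermis")
        r0 <- sample(seq.int(dTop + ry, dBot - ry), 1L)
        c0 <- sample(seq.int(rx + 1L, cfg@cols - rx), 1L)
        rr <- outer(((seq_len(cfg@rows) - r0) / ry)^2,
                    ((seq_len(cfg@cols) - c0) / rx)^2, `+`)
        sel <- rr <= 1
        if (any(occupied & sel)) next
        occupied <- occupied | sel
        labels[sel] <- 5L
        placed <- placed + 1L
      }
    })
  }
  LabelMap(labels, k = 6L, colorTable = clusterPalette(6L),
           classNames = TISSUE_CLASSES)
}

# Resolve the endmember table of a config (package defaults if unset).
configEndmembers <- function(cfg) {
  if (length(cfg@endmembers) == 0) return(defaultEndmembers())
  ems <- cfg@endmembers
  nm <- vapply(ems, function(e) e@name, "")
  names(ems) <- nm
  if (!all(TISSUE_CLASSES %in% nm))
    stop("custom endmember list must cover all classes: ",
         paste(TISSUE_CLASSES, collapse = ", "))
  ems[TISSUE_CLASSES]
}

#' Generate a synthetic skin phantom with ground truth
#'
#' Per pixel with tissue class `l`:
#' `cube[r, c, ] = t * E_l + a * P + B + eps`, where `t` is the section
#' thickness scale (Normal, truncated > 0), `a` the paraffin amplitude
#' (Normal, truncated >= 0), `P` the paraffin endmember, `B` a random
#' polynomial baseline on the axis rescaled to [-1, 1], and `eps` i.i.d.
#' Gaussian noise. Fully reproducible: the layout, thickness, paraffin,
#' baseline and noise fields each use a fixed substream derived from the
#' config seed.
#'
#' @param cfg a [PhantomConfig-class].
#' @return a [PhantomImage-class] carrying the image, the ground-truth label
#'   map and the true thickness/paraffin fields.
#' @export
generatePhantom <- function(cfg) {
  stopifnot(is(cfg, "PhantomConfig"))
  validObject(cfg)
  axis <- makeAxis(cfg@axisStart, cfg@axisEnd, cfg@axisStep)
  truth <- generateLayout(cfg)
  ems <- configEndmembers(cfg)
  E <- endmemberMatrix(ems, axis)                      # 6 x n
  P <- buildEndmember(paraffinEndmember(), axis)@absorbance
  npix <- cfg@rows * cfg@cols
  n <- length(axis)
  lab <- as.vector(truth@labels)                       # column-major pixels

  tv <- withSeed(deriveSeed(cfg@seed, 2L),
                 truncNorm(npix, cfg@thicknessMean, cfg@thicknessSd,
                           lower = 0, inclusive = FALSE))
  av <- withSeed(deriveSeed(cfg@seed, 3L),
                 truncNorm(npix, cfg@paraffinAmplitudeMean,
                           cfg@paraffinAmplitudeSd, lower = 0,
                           inclusive = TRUE))
  bcoef <- withSeed(deriveSeed(cfg@seed, 4L),
                    matrix(stats::rnorm(npix * (cfg@baselineOrder + 1L)),
                           nrow = npix) * cfg@baselineAmplitude)
  eps <- if (cfg@noiseSd > 0) {
    withSeed(deriveSeed(cfg@seed, 5L),
             matrix(stats::rnorm(npix * n, sd = cfg@noiseSd), nrow = npix))
  } else 0

  Q <- polyTerms(axis, cfg@baselineOrder)              # n x (order+1)
  Y <- E[lab + 1L, , drop = FALSE] * tv + outer(av, P) +
    tcrossprod(bcoef, Q) + eps
  img <- SpectralImage(
    axis = axis, cube = array(Y, dim = c(cfg@rows, cfg@cols, n)),
    pixelSize = cfg@pixelSize,
    meta = list(sample_id = sprintf("%s_seed%d", cfg@group, cfg@seed),
                group = cfg@group, seed = as.character(cfg@seed)))
  new("PhantomImage", image = img, truth = truth,
      trueThickness = matrix(tv, nrow = cfg@rows),
      trueParaffin = matrix(av, nrow = cfg@rows), config = cfg)
}

#' Generate a two-group phantom cohort
#'
#' `nPerGroup` WT and `nPerGroup` KO phantoms with distinct seeds derived
#' from one master seed; regenerating with the same master seed is
#' bit-identical, and adding phantoms does not perturb earlier ones.
#'
#' @param cfgWT,cfgKO [PhantomConfig-class] for each group (groups must be
#'   "WT" and "KO" respectively).
#' @param nPerGroup phantoms per group (>= 1).
#' @param seed master seed.
#' @return list of [PhantomImage-class], WT phantoms first; metadata
#'   `sample_id` is WT1..WTn, KO1..KOn.
#' @export
generateCohort <- function(cfgWT, cfgKO, nPerGroup, seed) {
  stopifnot(nPerGroup >= 1, cfgWT@group == "WT", cfgKO@group == "KO")
  out <- vector("list", 2L * nPerGroup)
  for (i in seq_len(nPerGroup)) {
    cw <- cfgWT; cw@seed <- deriveSeed(seed, i)
    ck <- cfgKO; ck@seed <- deriveSeed(seed, 1000L + i)
    pw <- generatePhantom(cw)
    pk <- generatePhantom(ck)
    pw@image@meta$sample_id <- sprintf("WT%d", i)
    pk@image@meta$sample_id <- sprintf("KO%d", i)
    out[[i]] <- pw
    out[[nPerGroup + i]] <- pk
  }
  out
}

#' Simulate a pure-paraffin calibration image
#'
#' Emulates the paraffin image acquired alongside the tissue sections: every
#' pixel is the paraffin endmember scaled by a truncated-normal amplitude,
#' with a small crystallinity component (CH2 scissoring doublet rebalancing)
#' and i.i.d. noise, so its principal components are meaningful.
#'
#' @param axis wavenumber axis (default full acquisition axis).
#' @param rows,cols image size (default 8 x 8).
#' @param amplitudeMean,amplitudeSd paraffin scale distribution.
#' @param crystallinitySd sd of the doublet-rebalancing component.
#' @param noiseSd i.i.d. noise sd (AU).
#' @param seed integer seed.
#' @return a [SpectralImage-class] of pure paraffin.
#' @export
simulateParaffinImage <- function(axis = makeAxis(), rows = 8, cols = 8,
                                  amplitudeMean = 1, amplitudeSd = 0.15,
                                  crystallinitySd = 0.05, noiseSd = 0.002,
                                  seed = 1) {
  P <- buildEndmember(paraffinEndmember(), axis)@absorbance
  cryst <- tissueEndmember("crystallinity",
                           list(band(1472, 10, 1), band(1462, 10, -1)))
  C <- buildEndmember(cryst, axis)@absorbance
  npix <- rows * cols
  n <- length(axis)
  Y <- withSeed(seed, {
    a <- truncNorm(npix, amplitudeMean, amplitudeSd, lower = 0)
    g <- stats::rnorm(npix, 0, crystallinitySd)
    eps <- if (noiseSd > 0) matrix(stats::rnorm(npix * n, sd = noiseSd),
                                   nrow = npix) else 0
    outer(a, P) + outer(g, C) + eps
  })
  SpectralImage(axis = axis, cube = array(Y, dim = c(rows, cols, n)),
                meta = list(sample_id = "paraffin"))
}
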
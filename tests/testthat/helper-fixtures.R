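# Shared fixtures: small phantoms and cohort helpers built in code.

# Compact noiseless config: a clean generative model for algebra tests.
# Overrides in ... win over the noiseless defaults.
cleanConfig <- function(rows = 16, cols = 16, seed = 1, ...) {
  args <- list(rows = rows, cols = cols, nHairBulbs = 0,
               paraffinAmplitudeMean = 0, paraffinAmplitudeSd = 0,
               baselineAmplitude = 0, thicknessSd = 0, noiseSd = 0,
               seed = seed)
  do.call(phantomConfig, utils::modifyList(args, list(...)))
}

# Small default-noise config that still fits hair bulbs.
smallConfig <- function(rows = 32, cols = 32, seed = 1, ...) {
  phantomConfig(rows = rows, cols = cols, seed = seed, ...)
}

processedRange <- c(800, 1800)

# Dewax a list of phantoms against a pooled mean target, as the pipeline does.
dewaxCohort <- function(phantoms, nComponents = 8, polyOrder = 2,
                        cMin = 0.2, paraffinSeed = 11) {
  cropped <- lapply(phantoms, function(p)
    cropSpectralRange(p@image, processedRange[1], processedRange[2]))
  axis <- wavenumbers(phantoms[[1]]@image)
  par <- cropSpectralRange(simulateParaffinImage(axis, seed = paraffinSeed),
                           processedRange[1], processedRange[2])
  pool <- poolPixels(cropped)
  target <- Spectrum(wavenumbers(cropped[[1]]), colMeans(pool$X), "cohort_mean")
  basis <- buildParaffinBasis(par, nComponents, polyOrder, target)
  lapply(cropped, function(im) dewaxImage(im, basis, maskRule(cMin))$image)
}

# Exhaustive K-means oracle: minimum within-cluster SS over all assignments
# of n points to k non-empty clusters (feasible for n <= 10, k <= 3).
exhaustiveInertia <- function(X, k) {
  n <- nrow(X)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    a <- as.integer(grid[i, ])
    if (length(unique(a)) < k) next
    inert <- 0
    for (j in seq_len(k)) {
      S <- X[a == j, , drop = FALSE]
      inert <- inert + sum(sweep(S, 2, colMeans(S))^2)
    }
    if (inert < best) best <- inert
  }
  best
}

# Two-sided p-value oracle: numerical quadrature of the t density.
tQuadP <- function(t, df) {
  if (!is.finite(t)) return(0)
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t), Inf,
                       rel.tol = 1e-13)$value
}
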
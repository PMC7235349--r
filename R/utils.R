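#' Derive a reproducible child seed from a master seed
#'
#' All randomised stages of the package draw their seeds from a single master
#' seed through this function, so that adding a stage (or a phantom) never
#' perturbs the random stream of an earlier one. The result is always a valid
#' 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param offset integer stream offset (>= 0); distinct offsets give distinct
#'   streams.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  # Weyl-style mixing mod the Mersenne prime 2^31 - 1; keeps seeds < 2^31
  m <- 2147483647
  s <- (abs(master) %% m) * 48271 + (abs(offset) %% m) * 16807 + 12345
  as.integer(s %% m)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

#' Deterministic qualitative palette for cluster maps
#'
#' Returns `k` maximally spread HCL hues at fixed chroma/luminance so that
#' repeated runs always render identical false-colour maps.
#'
#' @param k number of colours (>= 1).
#' @return integer matrix `k x 3` of RGB values in 0..255.
#' @export
clusterPalette <- function(k) {
  stopifnot(k >= 1)
  hues <- seq(15, 375, length.out = k + 1)[seq_len(k)]
  lum <- rep(c(60, 45, 75), length.out = k) # stagger luminance for large k
  cols <- grDevices::hcl(h = hues, c = 90, l = lum)
  rgb <- t(grDevices::col2rgb(cols))
  storage.mode(rgb) <- "integer"
  dimnames(rgb) <- list(NULL, c("r", "g", "b"))
  rgb
}

# Wavenumber axis scaled affinely to [-1, 1] (numerical conditioning of
# polynomial baseline terms).
scaledAxis <- function(axis) {
  rng <- range(axis)
  if (diff(rng) == 0) stop("axis has zero spectral extent")
  2 * (axis - rng[1]) / (rng[2] - rng[1]) - 1
}

# Matrix of polynomial terms x^j, j = 0..order, on the scaled axis.
polyTerms <- function(axis, order) {
  stopifnot(order >= 0)
  x <- scaledAxis(axis)
  outer(x, 0:order, `^`)
}

# Strict monotonicity check used by axis validation.
isStrictlyMonotonic <- function(v) {
  length(v) >= 2 && (all(diff(v) > 0) || all(diff(v) < 0))
}

# Largest-remainder apportionment of `total` integer units to `fractions`.
apportionRows <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
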
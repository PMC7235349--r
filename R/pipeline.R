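#' Default pipeline configuration
#'
#' Nested list mirroring the plain-text (YAML) config schema: phantom
#' geometry and generator settings, cohort size, EMSC dewaxing parameters,
#' K-means class counts, test level, correlation settings, master seed and
#' output directory. `clustering$k_list` defaults to both class counts used
#' for skin segmentation (5 and 10); `emsc$range` is the processed
#' fingerprint window 1800-800 cm^-1; `correlation$range` empty = full axis.
#'
#' @return named nested list of class "PipelineConfig".
#' @export
defaultPipelineConfig <- function() {
  cfg <- list(
    phantom = list(
      rows = 64L, cols = 64L, pixel_size_um = 6.25,
      axis_start_cm1 = 4000, axis_end_cm1 = 750, axis_step_cm1 = 2,
      dermis_thickness_ratio = 2.0,
      layer_fractions_wt = c(epidermis = 0.1, dermis = 0.3, hypodermis = 0.2,
                             muscle = 0.2, subcutaneous_fat = 0.2),
      n_hair_bulbs = 3L,
      paraffin_amplitude_mean = 0.3, paraffin_amplitude_sd = 0.1,
      baseline_order = 2L, baseline_amplitude = 0.02,
      thickness_mean = 1.0, thickness_sd = 0.1, noise_sd = 0.005),
    cohort = list(n_per_group = 3L),
    emsc = list(n_components = 8L, poly_order = 2L, c_min = 0.2,
                range = c(1800, 800)),
    clustering = list(k_list = c(5L, 10L), n_init = 20L),
    stats = list(alpha = 0.01),
    correlation = list(range = numeric(0), mode = "raw"),
    master_seed = 42L,
    output_dir = "irsh_run")
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

coerceField <- function(default, value, key) {
  if (is.numeric(default)) {
    v <- suppressWarnings(as.numeric(unlist(value)))
    if (any(is.na(v)))
      stop("config error: field '", key, "' is not numeric")
    if (is.integer(default)) v <- as.integer(round(v))
    if (!is.null(names(unlist(value)))) names(v) <- names(unlist(value))
    return(v)
  }
  if (is.character(default)) return(as.character(unlist(value)))
  value
}

mergeConfig <- function(default, user, prefix = "") {
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(default))
      stop("config error: unknown key '", full, "'")
    if (is.list(default[[key]]) && !is.null(names(default[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config error: '", full, "' must be a mapping")
      default[[key]] <- mergeConfig(default[[key]], user[[key]], full)
    } else {
      default[[key]] <- coerceField(default[[key]], user[[key]], full)
    }
  }
  default
}

checkConfig <- function(cfg) {
  kl <- cfg$clustering$k_list
  if (length(kl) == 0) stop("config error: k_list must be non-empty")
  if (any(kl < 2)) stop("config error: every k must be >= 2")
  a <- cfg$stats$alpha
  if (a <= 0 || a >= 1) stop("config error: alpha must be in (0, 1)")
  if (cfg$cohort$n_per_group < 1)
    stop("config error: n_per_group must be >= 1")
  if (length(cfg$emsc$range) != 2)
    stop("config error: emsc range must be two wavenumbers")
  if (length(cfg$correlation$range) %in% c(0, 2) == FALSE)
    stop("config error: correlation range must be empty or two wavenumbers")
  invisible(cfg)
}

#' Validate a pipeline config file
#'
#' Reads a plain-text hierarchical (YAML) config, fills defaults for missing
#' fields, coerces scalar types (e.g. alpha given as text), rejects unknown
#' keys and enforces constraints (non-empty k list with every k >= 2, alpha
#' in (0, 1)). An empty file yields the full default config.
#'
#' @param path config file path, or NULL.
#' @param config optionally, an already-parsed nested list instead of a file.
#' @return validated "PipelineConfig" list.
#' @export
validateConfig <- function(path = NULL, config = NULL) {
  if (is.null(config)) {
    config <- if (is.null(path)) list() else yaml::read_yaml(path)
    if (is.null(config)) config <- list()
  }
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  class(cfg) <- c("PipelineConfig", "list")
  checkConfig(cfg)
  cfg
}

phantomConfigFromPipeline <- function(p, group) {
  phantomConfig(rows = p$rows, cols = p$cols, pixelSize = p$pixel_size_um,
                axisStart = p$axis_start_cm1, axisEnd = p$axis_end_cm1,
                axisStep = p$axis_step_cm1, group = group,
                dermisThicknessRatio = p$dermis_thickness_ratio,
                layerFractionsWT = p$layer_fractions_wt,
                nHairBulbs = p$n_hair_bulbs,
                paraffinAmplitudeMean = p$paraffin_amplitude_mean,
                paraffinAmplitudeSd = p$paraffin_amplitude_sd,
                baselineOrder = p$baseline_order,
                baselineAmplitude = p$baseline_amplitude,
                thicknessMean = p$thickness_mean,
                thicknessSd = p$thickness_sd, noiseSd = p$noise_sd)
}

saveTruth <- function(phantom, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(phantom@truth@labels, path, "labels")
  rhdf5::h5write(phantom@trueThickness, path, "thickness")
  rhdf5::h5write(phantom@trueParaffin, path, "paraffin")
  invisible(path)
}

# Bundled synthetic type I collagen reference (dermis band model + paraffin);
# falls back to constructing it if the fixture is unavailable.
collagenReference <- function(axis = makeAxis()) {
  f <- system.file("extdata", "collagen_typeI_synthetic.csv", package = "irsh")
  if (nzchar(f)) {
    sp <- readSpectrumTable(f, name = "collagen_typeI")
    rng <- range(sp@axis)
    if (min(axis) >= rng[1] && max(axis) <= rng[2])
      return(resampleToAxis(sp, axis))
  }
  dermis <- buildEndmember(defaultEndmembers()$dermis, axis)
  par <- buildEndmember(paraffinEndmember(), axis)
  Spectrum(axis, dermis@absorbance + 0.3 * par@absorbance, "collagen_typeI")
}

writeTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

mdTable <- function(df, digits = 4) {
  fmt <- function(v) if (is.numeric(v)) signif(v, digits) else v
  df[] <- lapply(df, fmt)
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, rows)
}

#' Run the full spectral-histology pipeline
#'
#' Executes simulate -> dewax -> common K-means (per k) -> abundance ->
#' group comparison -> collagen correlation, writing every artefact under
#' `cfg$output_dir` (stage subdirectories, CSV tables, PNG maps, HDF5 cubes,
#' a CSV manifest and a Markdown report). Fully deterministic given
#' `cfg$master_seed`.
#'
#' @param cfg a validated "PipelineConfig" list (see [validateConfig()]).
#' @param verbose logical; emit per-stage progress messages.
#' @return a "RunReport" list: config echo, manifest, per-k abundance and
#'   comparison tables, dermis cluster ids, correlation summary, output
#'   hashes and the report path.
#' @export
runPipeline <- function(cfg = defaultPipelineConfig(), verbose = TRUE) {
  checkConfig(cfg)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- cfg$output_dir
  dirs <- c("simulate", "dewax", "compare", "correlate",
            sprintf("cluster_k%d", cfg$clustering$k_list))
  for (d in file.path(out, dirs)) dir.create(d, recursive = TRUE,
                                             showWarnings = FALSE)
  seed <- cfg$master_seed

  ## stage 1: simulate
  say("[simulate] %d phantoms per group, master seed %d",
      cfg$cohort$n_per_group, seed)
  cfgWT <- phantomConfigFromPipeline(cfg$phantom, "WT")
  cfgKO <- phantomConfigFromPipeline(cfg$phantom, "KO")
  cohort <- generateCohort(cfgWT, cfgKO, cfg$cohort$n_per_group, seed)
  ids <- vapply(cohort, function(p) p@image@meta$sample_id, "")
  groups <- vapply(cohort, function(p) p@image@meta$group, "")
  paths <- file.path(out, "simulate", paste0(ids, ".h5"))
  for (i in seq_along(cohort)) {
    saveImage(cohort[[i]]@image, paths[i], overwrite = TRUE)
    saveTruth(cohort[[i]], sub("\\.h5$", "_truth.h5", paths[i]))
  }
  manifest <- data.frame(id = ids, group = groups,
                         seed = vapply(cohort, function(p) p@config@seed, 1L),
                         path = file.path("simulate", paste0(ids, ".h5")))
  writeTable(manifest, file.path(out, "manifest.csv"))

  ## stage 2: dewax
  rng <- sort(cfg$emsc$range)
  say("[dewax] EMSC: %d paraffin components, poly order %d, range %g-%g",
      cfg$emsc$n_components, cfg$emsc$poly_order, rng[2], rng[1])
  axis <- makeAxis(cfg$phantom$axis_start_cm1, cfg$phantom$axis_end_cm1,
                   cfg$phantom$axis_step_cm1)
  paraffinImg <- simulateParaffinImage(axis, seed = deriveSeed(seed, 7001L))
  cropped <- lapply(cohort, function(p)
    cropSpectralRange(p@image, rng[1], rng[2]))
  paraffinCrop <- cropSpectralRange(paraffinImg, rng[1], rng[2])
  pool <- poolPixels(cropped)
  target <- Spectrum(cropped[[1]]@axis, colMeans(pool$X), "cohort_mean")
  basis <- buildParaffinBasis(paraffinCrop, cfg$emsc$n_components,
                              cfg$emsc$poly_order, target)
  rule <- maskRule(cMin = cfg$emsc$c_min)
  corrected <- vector("list", length(cohort))
  for (i in seq_along(cropped)) {
    dw <- dewaxImage(cropped[[i]], basis, rule)
    corrected[[i]] <- dw$image
    p <- file.path(out, "dewax", paste0(ids[i], "_dewaxed.h5"))
    saveImage(dw$image, p, overwrite = TRUE)
    rhdf5::h5createGroup(p, "emsc")
    rhdf5::h5write(dw$c, p, "emsc/c")
    rhdf5::h5write(dw$b, p, "emsc/b")
    rhdf5::h5write(dw$residualRms, p, "emsc/residual_rms")
    rhdf5::h5closeAll()
  }

  ## stages 3-4: cluster and compare per k
  truths <- lapply(cohort, function(p) p@truth)
  abundances <- list(); comparisons <- list(); dermisClusters <- list()
  for (k in cfg$clustering$k_list) {
    say("[cluster] common K-means, k = %d", k)
    cm <- commonKMeans(corrected, k, seed = deriveSeed(seed, 100L + k),
                       nInit = cfg$clustering$n_init)
    kdir <- file.path(out, sprintf("cluster_k%d", k))
    for (i in seq_along(cm$labelMaps)) {
      renderLabelMap(cm$labelMaps[[i]], file.path(kdir, paste0(ids[i], ".png")))
      lp <- file.path(kdir, paste0(ids[i], "_labels.h5"))
      if (file.exists(lp)) unlink(lp)
      rhdf5::h5createFile(lp)
      rhdf5::h5write(cm$labelMaps[[i]]@labels, lp, "labels")
      rhdf5::h5closeAll()
    }
    ab <- abundanceTable(cm$labelMaps, ids, groups)
    sums <- tapply(ab$percent, ab$image_id, sum)
    stopifnot(all(abs(sums - 100) < 1e-9)) # cross-stage consistency
    writeTable(ab, file.path(out, sprintf("abundance_k%d.csv", k)))
    cmp <- compareAll(ab, alpha = cfg$stats$alpha)
    writeTable(cmp, file.path(out, "compare", sprintf("comparisons_k%d.csv", k)))
    kk <- as.character(k)
    abundances[[kk]] <- ab
    comparisons[[kk]] <- cmp
    dermisClusters[[kk]] <- clusterForClass(cm$labelMaps, truths, "dermis")
  }

  ## stage 5: correlate
  say("[correlate] reference: synthetic type I collagen, mode %s",
      cfg$correlation$mode)
  ref <- collagenReference(axis)
  crng <- cfg$correlation$range
  corrStats <- list()
  for (i in seq_along(cohort)) {
    srcImg <- if (identical(cfg$correlation$mode, "dewaxed"))
      corrected[[i]] else cohort[[i]]@image
    refUse <- if (identical(cfg$correlation$mode, "dewaxed"))
      buildEndmember(defaultEndmembers()$dermis, srcImg@axis) else ref
    cmap <- if (length(crng) == 2)
      correlateImage(srcImg, refUse, min(crng), max(crng),
                     mode = cfg$correlation$mode)
    else correlateImage(srcImg, refUse, mode = cfg$correlation$mode)
    renderCorrelation(cmap, file.path(out, "correlate", paste0(ids[i], ".png")))
    dsel <- truths[[i]]@labels == 1L # dermis
    corrStats[[i]] <- data.frame(
      id = ids[i], group = groups[i],
      median_r_dermis = stats::median(cmap@rRaw[dsel], na.rm = TRUE),
      median_r_fat = stats::median(cmap@rRaw[truths[[i]]@labels == 4L],
                                   na.rm = TRUE))
  }
  corrSummary <- do.call(rbind, corrStats)
  writeTable(corrSummary, file.path(out, "correlate", "correlation_summary.csv"))

  ## stage 6: report
  csvs <- list.files(out, pattern = "\\.csv$", recursive = TRUE,
                     full.names = TRUE)
  hashes <- tools::md5sum(sort(csvs))
  names(hashes) <- sub(paste0("^", out, "/?"), "", names(hashes))
  lines <- c("# IRSH pipeline report", "",
             sprintf("- master seed: %d", seed),
             sprintf("- phantoms: %d WT + %d KO, %d x %d px",
                     cfg$cohort$n_per_group, cfg$cohort$n_per_group,
                     cfg$phantom$rows, cfg$phantom$cols),
             sprintf("- EMSC: %d paraffin components, poly order %d, cMin %.2f, range %g-%g cm-1",
                     cfg$emsc$n_components, cfg$emsc$poly_order,
                     cfg$emsc$c_min, rng[2], rng[1]),
             sprintf("- K-means class counts: %s",
                     paste(cfg$clustering$k_list, collapse = ", ")), "")
  for (kk in names(comparisons)) {
    lines <- c(lines, sprintf("## Group comparison, k = %s", kk),
               sprintf("Dermis cluster (matched to ground truth): %d",
                       dermisClusters[[kk]]), "",
               mdTable(comparisons[[kk]]), "")
  }
  lines <- c(lines, "## Correlation with type I collagen", "",
             mdTable(corrSummary), "", "## Output hashes (md5)", "",
             sprintf("- `%s`: %s", names(hashes), hashes))
  pngs <- list.files(out, pattern = "\\.png$", recursive = TRUE,
                     full.names = TRUE)
  stopifnot(all(file.exists(c(csvs, pngs))))
  reportPath <- file.path(out, "report.md")
  writeLines(lines, reportPath)
  say("[report] %s", reportPath)

  structure(list(config = cfg, manifest = manifest, abundance = abundances,
                 comparisons = comparisons, dermisClusters = dermisClusters,
                 correlationSummary = corrSummary, hashes = hashes,
                 reportPath = reportPath, outputDir = out),
            class = "RunReport")
}
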
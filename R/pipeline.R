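# End-to-end orchestration: stack -> masks -> PIV -> strain -> compartments
# -> statistics -> Kelvin-Voigt fit, with YAML configuration, a
# machine-readable manifest and deterministic outputs.

#' Build a run configuration
#'
#' Defaults mirror the acquisition protocol the analysis was designed for:
#' 4 frames/s, 20 s baseline / 10 s stimulation / 30 s recovery,
#' 0.1233 um/px, PIV 32 px windows at 75 % overlap down to a 4 px grid,
#' 6 px border cutoff, 7 density bins, 4 px shells.
#'
#' @param stack an [ImageStack-class], or path to a multi-frame TIFF.
#' @param stain optional stain [ImageStack-class] / TIFF path / single
#'   matrix for nucleolus detection.
#' @param outDir output directory (created if missing); NULL disables
#'   file output.
#' @param pixelSize um/px (used when reading TIFFs).
#' @param frameInterval s.
#' @param tOn,tOff stimulation window, s.
#' @param piv a [PIVConfig-class].
#' @param borderCutoff px.
#' @param nBins density classes.
#' @param shellThickness px.
#' @param nShells number of perinucleolar shells.
#' @param detectCHC also segment/track the CHC.
#' @param seed RNG seed recorded in the manifest.
#' @return a list of class "RunConfig".
#' @export
runConfig <- function(stack, stain = NULL, outDir = NULL,
                      pixelSize = 0.1233, frameInterval = 0.25,
                      tOn = 20, tOff = 30, piv = pivConfig(),
                      borderCutoff = 6, nBins = 7L, shellThickness = 4,
                      nShells = 3L, detectCHC = FALSE, seed = 1L) {
  structure(list(stack = stack, stain = stain, outDir = outDir,
                 pixelSize = pixelSize, frameInterval = frameInterval,
                 tOn = tOn, tOff = tOff, piv = piv,
                 borderCutoff = borderCutoff, nBins = as.integer(nBins),
                 shellThickness = shellThickness,
                 nShells = as.integer(nShells), detectCHC = detectCHC,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Recognised keys match the arguments of [runConfig()]; `piv` may be a
#' mapping with pass_windows/overlap/global_k/local_threshold/min_snr.
#'
#' @param path YAML file path.
#' @return a "RunConfig" list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pv <- pivConfig()
  if (!is.null(y$piv)) {
    pv <- pivConfig(
      passWindows = if (!is.null(y$piv$pass_windows)) y$piv$pass_windows
                    else c(32L, 16L),
      overlap = if (!is.null(y$piv$overlap)) y$piv$overlap else 0.75,
      globalK = if (!is.null(y$piv$global_k)) y$piv$global_k else 3,
      localThreshold = if (!is.null(y$piv$local_threshold))
        y$piv$local_threshold else 2.5,
      minSNR = if (!is.null(y$piv$min_snr)) y$piv$min_snr else 1.3)
  }
  args <- y[setdiff(names(y), "piv")]
  args$piv <- pv
  do.call(runConfig, args)
}

.loadStack <- function(x, pixelSize, frameInterval, channel) {
  if (is(x, "ImageStack")) return(x)
  if (is.matrix(x)) {
    return(new("ImageStack", frames = array(x, c(dim(x), 1L)),
               timestamps = 0, pixelSize = pixelSize, channel = channel))
  }
  fr <- tiff::readTIFF(x, all = TRUE, as.is = FALSE)
  if (is.matrix(fr)) fr <- list(fr)
  arr <- array(0, c(dim(fr[[1]])[1:2], length(fr)))
  for (i in seq_along(fr)) {
    m <- fr[[i]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    arr[, , i] <- m
  }
  new("ImageStack", frames = arr,
      timestamps = (seq_along(fr) - 1) * frameInterval,
      pixelSize = pixelSize, channel = channel)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

.writeMatrixTIFF <- function(m, path) {
  rng <- range(m, na.rm = TRUE)
  scl <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  scl[!is.finite(scl)] <- 0
  tiff::writeTIFF(scl, path, bits.per.sample = 16L)
  rng
}

#' Run the full chromatin-deformation pipeline
#'
#' Executes segmentation, PIV against the t = 0 reference, strain maps at
#' peak deformation (the last stimulation frame), compartment labelling,
#' compartment strain and shell displacement tables, and the Kelvin-Voigt
#' fit of the image-difference dynamics. When `outDir` is set, writes CSV
#' tables, normalised 16-bit TIFF maps (value ranges in the JSON report)
#' and a YAML manifest with the configuration hash; outputs are
#' deterministic for identical inputs and seed.
#'
#' @param config a "RunConfig" list from [runConfig()] /
#'   [readRunConfig()].
#' @return (invisibly) a list with masks, fields, strain, labels, tables,
#'   the Kelvin-Voigt fit, the peak-frame index and output paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  stack <- .stage("load",
                  .loadStack(config$stack, config$pixelSize,
                             config$frameInterval, "chromatin"))
  frame0 <- getFrame(stack, 1)
  nuc <- .stage("segment", segmentNucleus(frame0))
  interior <- .stage("segment", interiorMask(nuc, config$borderCutoff))
  stainFrame <- NULL
  if (!is.null(config$stain)) {
    st <- .loadStack(config$stain, config$pixelSize, config$frameInterval,
                     "stain")
    stainFrame <- getFrame(st, 1)
  } else {
    message("no stain channel: nucleolus and shell statistics skipped")
  }
  labels <- .stage("compartments",
    compartmentLabels(frame0, stainFrame, pixelSize = pixelSize(stack),
                      borderCutoff = config$borderCutoff,
                      nBins = config$nBins,
                      shellThickness = config$shellThickness,
                      nShells = config$nShells,
                      detectCHC = config$detectCHC,
                      nucleusMaskOverride = nuc))
  fields <- .stage("piv", displacementSequence(stack, config$piv, nuc))
  ts <- timestamps(stack)
  peakIdx <- max(which(ts <= config$tOff))    # last stimulation frame
  peakField <- fields[[max(peakIdx - 1, 1)]]
  strain <- .stage("strain", strainFromDisplacement(peakField))
  shape <- dim(frame0)
  hydroMap <- .stage("strain",
    upsampleToImage(strain, shape, "hydro", mask = interior))
  shearMap <- .stage("strain",
    upsampleToImage(strain, shape, "shear", mask = interior))
  dispMap <- .stage("strain",
    displacementMagnitudeMap(peakField, shape, mask = interior))
  absTab <- .stage("stats",
    compartmentStrainStats(hydroMap, labels, "absolute"))
  totTab <- .stage("stats",
    compartmentStrainStats(hydroMap, labels, "total"))
  shellTab <- if (any(nucleolusMask(labels))) {
    .stage("stats", shellDisplacementStats(dispMap, labels))
  } else {
    NULL
  }
  series <- .stage("kinetics",
    imageDifferenceSeries(stack, nuc, config$tOn, config$tOff))
  kv <- .stage("kinetics", fitKelvinVoigt(series))
  if (kv@flat) message("Kelvin-Voigt fit flagged flat (no deformation)")
  paths <- NULL
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outDir, f)
    utils::write.csv(absTab, p("compartment_strain_absolute.csv"),
                     row.names = FALSE)
    utils::write.csv(totTab, p("compartment_strain_total.csv"),
                     row.names = FALSE)
    if (!is.null(shellTab))
      utils::write.csv(shellTab, p("shell_displacements.csv"),
                       row.names = FALSE)
    utils::write.csv(data.frame(t = series@t, value = series@value),
                     p("image_difference.csv"), row.names = FALSE)
    rngH <- .writeMatrixTIFF(hydroMap, p("strain_hydro.tif"))
    rngS <- .writeMatrixTIFF(shearMap, p("strain_shear.tif"))
    rngD <- .writeMatrixTIFF(dispMap, p("displacement_um.tif"))
    report <- list(
      kelvinVoigt = if (kv@flat) list(flat = TRUE) else
        list(E = kv@E, tauC = kv@tauC, tauR = kv@tauR,
             amplitude = kv@amplitude, rmse = kv@fitRMSE),
      peakFrame = peakIdx,
      mapRanges = list(hydro = rngH, shear = rngS, displacement = rngD))
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         digits = NA)
    cfgForHash <- config
    cfgForHash$stack <- if (is.character(config$stack)) config$stack else
      "in-memory"
    cfgForHash$stain <- if (is.character(config$stain)) config$stain else
      if (is.null(config$stain)) NULL else "in-memory"
    cfgTxt <- tempfile()
    writeLines(utils::capture.output(utils::str(cfgForHash)), cfgTxt)
    manifest <- list(
      package = "nucleostrain",
      version = as.character(utils::packageVersion("nucleostrain")),
      seed = config$seed,
      configHash = unname(tools::md5sum(cfgTxt)),
      inputHash = if (is.character(config$stack))
        unname(tools::md5sum(config$stack)) else NA)
    yaml::write_yaml(manifest, p("manifest.yaml"))
    unlink(cfgTxt)
    paths <- list(outDir = config$outDir)
  }
  invisible(list(stack = stack, nucleusMask = nuc, interiorMask = interior,
                 labels = labels, fields = fields, peakFrame = peakIdx,
                 strain = strain, hydroMap = hydroMap, shearMap = shearMap,
                 dispMap = dispMap, compartmentAbsolute = absTab,
                 compartmentTotal = totTab, shellDisplacements = shellTab,
                 imageDifference = series, kelvinVoigt = kv, paths = paths))
}
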
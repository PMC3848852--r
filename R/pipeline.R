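#' @include io.R
NULL

#' Process a single acquisition through the post-processing chain
#'
#' Runs one velocity-encoded (or pre-reconstructed) acquisition through the
#' full chain: multi-coil combination, eddy-current phase correction (when
#' static-tissue annotations are present), nine-point decode, cycle
#' trimming, contour interpolation and segment-model construction, bulk
#' motion subtraction, cardiopolar decomposition, waveform extraction, key
#' timepoint detection, dual-origin Fourier tracking, and circumferential
#' strain (trajectory- and polygon-derived).
#'
#' @param acq an [EncodedAcquisition-class], [VelocityCine-class], or a
#'   container path for [readAcquisition()]
#' @param annotations a [ContourSet-class] or annotation file path
#' @param nSegments angular segments (default 32)
#' @param direction segment counting direction
#' @param eccOrder polynomial order of the eddy-current correction
#' @param label free-text label carried into outputs
#' @return a processed-run bundle: a list with elements `label`, `model`,
#'   `waveforms` (radial/tangential/longitudinal [WaveformSet-class]s),
#'   `key` ([KeyTimepoints-class]), `lumenAreaMm2`, `strain` (dual-origin
#'   averaged [StrainCurveSet-class]), `strainED`, `strainES`, `maskStrain`,
#'   `timeMs`, `frameMs`, `nValidTrajectories`
#' @export
processAcquisition <- function(acq, annotations, nSegments = 32L,
                               direction = "ccw", eccOrder = 1L,
                               label = "run") {
  if (is.character(acq)) acq <- readAcquisition(acq)
  if (is.character(annotations)) annotations <- readAnnotations(annotations)
  if (methods::is(acq, "EncodedAcquisition")) {
    d <- dim(acq@data)
    staticMask <- if (length(annotations@staticRegions))
      .rasterizePolys(annotations@staticRegions, d[3], acq@pixelMm)
    exclMask <- if (length(annotations@foldover))
      .rasterizePolys(annotations@foldover, d[3], acq@pixelMm)
    cine <- reconstructVelocities(acq, staticMask, exclMask, eccOrder)
  } else cine <- acq
  # trim to one cardiac cycle
  nC <- cine@nFramesCycle
  if (dim(cine@velocity)[1] > nC) {
    cine <- methods::new("VelocityCine",
      velocity = cine@velocity[seq_len(nC), , , , drop = FALSE],
      magnitude = cine@magnitude[seq_len(nC), , , drop = FALSE],
      wrapped = cine@wrapped[seq_len(nC), , , drop = FALSE],
      vencCmS = cine@vencCmS, frameMs = cine@frameMs,
      pixelMm = cine@pixelMm, nFramesCycle = nC)
  }
  gridSize <- dim(cine@velocity)[2]
  polys <- interpolateContours(annotations, nC)
  model <- buildSegmentModel(polys, annotations, gridSize, cine@pixelMm,
                             nSegments, direction, wrapped = cine@wrapped)
  cine <- subtractBulkMotion(cine, model)
  polar <- toCardiopolar(cine, model)
  wf <- list(radial = extractWaveforms(polar, model, "radial"),
             tangential = extractWaveforms(polar, model, "tangential"),
             longitudinal = extractWaveforms(polar, model, "longitudinal"))
  areas <- lumenArea(model)
  key <- detectKeyTimepoints(wf$radial, areas, annotations@tLastDiastole)
  tED <- key@tED
  trED <- filterTrajectories(fourierTrack(cine, model, tED), model)
  trES <- filterTrajectories(fourierTrack(cine, model, key@tEndSystole),
                             model)
  scED <- circumferentialStrain(segmentPaths(trED, nSegments), tED,
                                cine@frameMs, origin = "ED")
  scES <- circumferentialStrain(segmentPaths(trES, nSegments), tED,
                                cine@frameMs, origin = "ES")
  strain <- averageDualOrigin(scED, scES)
  list(label = label, model = model, waveforms = wf, key = key,
       lumenAreaMm2 = areas, strain = strain, strainED = scED,
       strainES = scES, maskStrain = maskStrain(model),
       timeMs = wf$radial@timeMs, frameMs = cine@frameMs,
       nValidTrajectories = c(ED = sum(trED@valid), ES = sum(trES@valid)))
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates the end-to-end post-processing of one dataset: each listed
#' acquisition is processed independently ([processAcquisition()]); with two
#' acquisitions the runs are temporally aligned and segment-wise averaged
#' ([alignAndAverage()]); regional indices are computed; and waveform,
#' strain and index tables are written as CSV together with a processing
#' log.  Deterministic for a fixed configuration and seed.
#'
#' @param config a configuration list or the path of a YAML file with
#'   fields: `acquisitions` (list of `container` + `annotations` paths; one
#'   or two entries), and optionally `n_segments` (default 32, must be even
#'   and >= 4), `direction` (`ccw`/`cw`), `ecc_order`, `sd`
#'   (`sample`/`population`), `stretch` (`min`/`max`/`step`), `seed`,
#'   `out_dir`
#' @param outDir overrides the configured output directory
#' @return (invisibly) a list with the averaged `run`, the `indices`, the
#'   per-acquisition bundles and the output file paths
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  nSeg <- as.integer(config$n_segments %||% 32L)
  if (nSeg < 4L || nSeg %% 2L != 0L)
    stop("n_segments must be even and at least 4")
  direction <- config$direction %||% "ccw"
  eccOrder <- as.integer(config$ecc_order %||% 1L)
  sdSample <- !identical(config$sd, "population")
  seed <- as.integer(config$seed %||% 1L)
  outDir <- outDir %||% config$out_dir %||% "."
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  acqs <- config$acquisitions
  if (is.null(acqs) || !length(acqs)) stop("no acquisitions configured")
  for (a in acqs) {
    for (p in c(a$container, a$annotations))
      if (!file.exists(p)) stop("configured file does not exist: ", p)
  }
  log <- c(sprintf("tpmcmr pipeline | %d acquisition(s) | %d segments (%s)",
                   length(acqs), nSeg, direction),
           sprintf("ecc_order=%d sd=%s seed=%d", eccOrder,
                   if (sdSample) "sample" else "population", seed))
  set.seed(seed)
  runs <- list()
  for (i in seq_along(acqs)) {
    t0 <- proc.time()[["elapsed"]]
    runs[[i]] <- processAcquisition(acqs[[i]]$container,
                                    acqs[[i]]$annotations,
                                    nSegments = nSeg, direction = direction,
                                    eccOrder = eccOrder,
                                    label = sprintf("acq%d", i))
    log <- c(log, sprintf(
      "acq%d: %s | valid trajectories ED=%d ES=%d | %.1f s", i,
      acqs[[i]]$container, runs[[i]]$nValidTrajectories["ED"],
      runs[[i]]$nValidTrajectories["ES"],
      proc.time()[["elapsed"]] - t0))
  }
  if (length(runs) == 2L) {
    st <- config$stretch
    grid <- seq(st$min %||% 0.80, st$max %||% 1.25, by = st$step %||% 0.005)
    aa <- alignAndAverage(runs[[1]], runs[[2]], grid)
    run <- aa$run
    log <- c(log, sprintf(
      "aligned acquisitions: stretch=%.3f, global radial correlation=%.4f",
      aa$stretch, aa$correlation))
  } else {
    run <- runs[[1]]
    log <- c(log, "single acquisition: skipping temporal alignment and averaging")
  }
  indices <- regionalIndices(run$waveforms$radial, run$strain, run$key,
                             sample = sdSample)
  paths <- list(
    waveforms = file.path(outDir, "waveforms.csv"),
    strain = file.path(outDir, "strain.csv"),
    indices = file.path(outDir, "indices.csv"),
    log = file.path(outDir, "pipeline.log"))
  .writeWaveformsCsv(run$waveforms, paths$waveforms)
  .writeStrainCsv(run$strain, run$maskStrain, paths$strain)
  utils::write.csv(as.data.frame(indices), paths$indices, row.names = FALSE)
  log <- c(log, sprintf("wrote %s", unlist(paths)))
  writeLines(log, paths$log)
  invisible(list(run = run, indices = indices, runs = runs, paths = paths))
}

.writeWaveformsCsv <- function(wf, path) {
  rows <- list()
  for (nm in names(wf)) {
    w <- wf[[nm]]
    nSeg <- nrow(w@regional)
    nF <- length(w@global)
    rows[[length(rows) + 1]] <- data.frame(
      component = nm, segment = "global", frame = seq_len(nF),
      time_ms = w@timeMs, velocity_cm_s = w@global)
    rows[[length(rows) + 1]] <- data.frame(
      component = nm,
      segment = as.character(rep(0:(nSeg - 1), each = nF)),
      frame = rep(seq_len(nF), nSeg),
      time_ms = rep(w@timeMs, nSeg),
      velocity_cm_s = as.vector(t(w@regional)))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

.writeStrainCsv <- function(strain, maskStr, path) {
  nSeg <- nrow(strain@sc)
  nF <- ncol(strain@sc)
  df <- rbind(
    data.frame(segment = "global", frame = seq_len(nF),
               time_ms = strain@timeMs,
               sc_percent = 100 * strain@globalSc),
    data.frame(segment = as.character(rep(0:(nSeg - 1), each = nF)),
               frame = rep(seq_len(nF), nSeg),
               time_ms = rep(strain@timeMs, nSeg),
               sc_percent = 100 * as.vector(t(strain@sc))),
    data.frame(segment = "mask_global", frame = maskStr$frame,
               time_ms = strain@timeMs[maskStr$frame],
               sc_percent = 100 * maskStr$sc_g))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Write a phantom dataset to disk
#'
#' Generates the synthetic acquisition(s) described by a [PhantomSpec-class]
#' and writes: the encoded container(s), a plain-text annotation sidecar per
#' acquisition, and the analytic ground truth (as a serialized
#' [GroundTruth-class], `<stem>_truth.rds`).  With `secondAcquisition` a
#' rotated acquisition with an independent ghost realization is written as
#' `<stem>2.rds`.
#'
#' @param spec a [PhantomSpec-class]
#' @param stem output path stem (files `<stem>.rds`, `<stem>.annot`, ...)
#' @param encoded write encoded multi-coil containers (TRUE) or plain
#'   velocity-cine containers (FALSE)
#' @param secondAcquisition also write the rotated second acquisition
#' @param eddyRampsRad optional 9 x 3 per-encoding phase ramps
#' @return (invisibly) the list of files written
#' @export
writePhantomDataset <- function(spec, stem, encoded = TRUE,
                                secondAcquisition = FALSE,
                                eddyRampsRad = NULL) {
  truth <- makeMotionModel(spec)
  files <- character()
  writeOne <- function(rot, idx, suffix) {
    cine <- renderVelocityCine(truth, rotationDeg = rot)
    obj <- if (encoded)
      encodeAcquisition(cine, spec, rotationDeg = rot, acqIndex = idx,
                        eddyRampsRad = eddyRampsRad)
    else cine
    cpath <- paste0(stem, suffix, ".rds")
    apath <- paste0(stem, suffix, ".annot")
    writeAcquisition(obj, cpath)
    writeAnnotations(phantomAnnotations(truth, rotationDeg = rot), apath)
    c(cpath, apath)
  }
  files <- c(files, writeOne(0, 1L, ""))
  if (secondAcquisition)
    files <- c(files, writeOne(spec@fovRotationDeg, 2L, "2"))
  tpath <- paste0(stem, "_truth.rds")
  saveRDS(truth, tpath)
  invisible(c(files, tpath))
}
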
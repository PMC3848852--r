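#' @include AllClasses.R
NULL

#' Subtract bulk in-plane motion
#'
#' Removes bulk cardiac motion by subtracting, per frame, the mean in-plane
#' velocity vector over the myocardial mask from every pixel.  The
#' through-plane component is untouched.
#'
#' @param cine a [VelocityCine-class]
#' @param model a [SegmentModel-class]
#' @return the corrected [VelocityCine-class]
#' @export
subtractBulkMotion <- function(cine, model) {
  nF <- dim(cine@velocity)[1]
  for (f in seq_len(nF)) {
    m <- model@mask[f, , ]
    vx <- cine@velocity[f, , , 1]
    vy <- cine@velocity[f, , , 2]
    cine@velocity[f, , , 1] <- vx - mean(vx[m])
    cine@velocity[f, , , 2] <- vy - mean(vy[m])
  }
  cine
}

#' Cardiopolar velocity decomposition
#'
#' Decomposes the in-plane velocity of every pixel into a radial component
#' along the unit vector from the per-frame LV centre to the pixel -- with
#' motion towards the centre (contraction) reported as positive -- and an
#' orthogonal tangential component; the through-plane (longitudinal)
#' component is passed through unchanged.  A pixel exactly at the LV centre
#' has no defined direction; its radial and tangential values are set to 0.
#'
#' @param cine a (bulk-corrected) [VelocityCine-class]
#' @param model a [SegmentModel-class]
#' @return a [CardiopolarCine-class]
#' @export
toCardiopolar <- function(cine, model) {
  d <- dim(cine@velocity)
  nF <- d[1]; ny <- d[2]; nx <- d[3]
  co <- .pixelCoords(nx, cine@pixelMm)
  px <- matrix(rep(co, each = ny), ny, nx)
  py <- matrix(rep(.pixelCoords(ny, cine@pixelMm), times = nx), ny, nx)
  rad <- array(0, c(nF, ny, nx))
  tang <- array(0, c(nF, ny, nx))
  for (f in seq_len(nF)) {
    dx <- px - model@center[f, 1]
    dy <- py - model@center[f, 2]
    r <- sqrt(dx^2 + dy^2)
    atCenter <- r < 1e-12
    r[atCenter] <- 1
    ux <- dx / r; uy <- dy / r
    vx <- cine@velocity[f, , , 1]
    vy <- cine@velocity[f, , , 2]
    rr <- -(vx * ux + vy * uy)      # contraction positive
    tt <- vx * (-uy) + vy * ux
    rr[atCenter] <- 0
    tt[atCenter] <- 0
    rad[f, , ] <- rr
    tang[f, , ] <- tt
  }
  methods::new("CardiopolarCine", radial = rad, tangential = tang,
               longitudinal = cine@velocity[, , , 3, drop = TRUE],
               frameMs = cine@frameMs, pixelMm = cine@pixelMm)
}

#' Extract global and regional waveforms
#'
#' Per frame, the regional value of each segment is the mean over that
#' segment's masked pixels, and the global value the mean over all masked
#' pixels (not the mean of segment means).  A segment empty at some frame
#' gets the value of the nearest frame where it has data, and is flagged in
#' the `imputed` slot.
#'
#' @param polar a [CardiopolarCine-class]
#' @param model a [SegmentModel-class]
#' @param component which component to extract
#' @return a [WaveformSet-class]
#' @export
extractWaveforms <- function(polar, model,
                             component = c("radial", "tangential",
                                           "longitudinal")) {
  component <- match.arg(component)
  arr <- slot(polar, component)
  nF <- dim(arr)[1]
  nSeg <- model@nSegments
  glob <- numeric(nF)
  reg <- matrix(NA_real_, nSeg, nF)
  for (f in seq_len(nF)) {
    vals <- arr[f, , ]
    m <- model@mask[f, , ]
    glob[f] <- mean(vals[m])
    seg <- model@segmentMap[f, , ][m]
    ms <- tapply(vals[m], factor(seg, levels = 0:(nSeg - 1)), mean)
    reg[, f] <- as.numeric(ms)
  }
  imputed <- is.na(reg)
  if (any(imputed)) {
    for (s in seq_len(nSeg)) {
      miss <- which(is.na(reg[s, ]))
      if (length(miss) == 0 || length(miss) == nF) next
      have <- which(!is.na(reg[s, ]))
      for (f in miss) reg[s, f] <- reg[s, have[which.min(abs(have - f))]]
    }
  }
  methods::new("WaveformSet", global = glob, regional = reg,
               component = component,
               timeMs = (seq_len(nF) - 1) * polar@frameMs,
               imputed = imputed)
}

#' Detect key cardiac timepoints
#'
#' Peak systole is the frame of maximum global radial velocity (contraction
#' positive); end-systole the frame of minimum LV lumen (endocardial
#' polygon) area.  Ties resolve to the earliest frame.  End-diastole comes
#' from the annotations.
#'
#' @param radial a radial [WaveformSet-class]
#' @param lumenAreaMm2 per-frame endocardial polygon areas (mm^2)
#' @param tED annotated end-diastolic frame index
#' @return a [KeyTimepoints-class]
#' @export
detectKeyTimepoints <- function(radial, lumenAreaMm2, tED = 1L) {
  methods::new("KeyTimepoints",
               tPeakSystole = as.integer(which.max(radial@global)),
               tEndSystole = as.integer(which.min(lumenAreaMm2)),
               tED = as.integer(tED))
}

# periodic resampling of a cyclic curve y (sampled at tx, period) at times tq
.resamplePeriodic <- function(tx, y, periodMs, tq) {
  f <- .periodicSplineFun(tx, y, periodMs)
  f(tq %% periodMs)
}

#' Temporally align and average two processed acquisitions
#'
#' The two acquisitions of a rotating-FOV protocol are processed
#' independently (each with its own papillary-anchored segment division) and
#' combined as the last step.  To compensate slight heart-rate differences,
#' the second run's time axis is stretched by the factor -- searched over a
#' grid -- that maximizes the Pearson correlation between the two global
#' radial velocity waveforms (cubic-spline resampling); all of run 2's
#' segment-wise curves are then resampled onto run 1's time base at that
#' stretch and averaged segment-by-segment (segment s with segment s, both
#' anchored at the papillary landmarks, which is how the rotated FOV is
#' reconciled).
#'
#' @param run1,run2 processed-run bundles as returned by [processAcquisition()]
#' @param stretchGrid candidate stretch factors (default 0.80 to 1.25 in
#'   steps of 0.005)
#' @return a list: `run` (the averaged bundle on run 1's time base),
#'   `stretch` (chosen factor) and `correlation` (global radial Pearson r at
#'   that factor).  A maximum correlation below 0.5 triggers a warning that
#'   the acquisitions are inconsistent.
#' @export
alignAndAverage <- function(run1, run2,
                            stretchGrid = seq(0.80, 1.25, by = 0.005)) {
  t1 <- run1$timeMs
  g1 <- run1$waveforms$radial@global
  t2 <- run2$timeMs
  g2 <- run2$waveforms$radial@global
  T2 <- length(t2) * run2$frameMs
  best <- -Inf; bestS <- 1
  for (s in stretchGrid) {
    # run 2 resampled on run 1's frame times scaled by the stretch factor
    keep <- t1 * s <= max(t2)
    if (sum(keep) < 3) next
    v <- .resamplePeriodic(t2, g2, T2, t1[keep] * s)
    r <- .safeCor(g1[keep], v)
    if (!is.na(r) && r > best) { best <- r; bestS <- s }
  }
  if (best < 0.5)
    warning("acquisitions inconsistent: maximum global radial correlation ",
            signif(best, 3))
  tq <- t1 * bestS
  resampleWf <- function(w1, w2) {
    reg <- w2@regional
    regR <- t(apply(reg, 1, function(y) .resamplePeriodic(t2, y, T2, tq)))
    glR <- .resamplePeriodic(t2, w2@global, T2, tq)
    methods::new("WaveformSet", global = (w1@global + glR) / 2,
                 regional = (w1@regional + regR) / 2,
                 component = w1@component, timeMs = t1,
                 imputed = w1@imputed)
  }
  wf <- lapply(names(run1$waveforms), function(nm)
    resampleWf(run1$waveforms[[nm]], run2$waveforms[[nm]]))
  names(wf) <- names(run1$waveforms)
  strain <- NULL
  if (!is.null(run1$strain) && !is.null(run2$strain)) {
    sc2 <- t(apply(run2$strain@sc, 1, function(y) {
      if (anyNA(y)) return(rep(NA_real_, length(tq)))
      .resamplePeriodic(t2, y, T2, tq)
    }))
    scAvg <- (run1$strain@sc + sc2) / 2
    na1 <- is.na(run1$strain@sc); na2 <- is.na(sc2)
    scAvg[na1 & !na2] <- sc2[na1 & !na2]
    scAvg[na2 & !na1] <- run1$strain@sc[na2 & !na1]
    # re-reference so the end-diastolic frame stays exactly zero
    tEDi <- run1$strain@tED
    scAvg <- (1 + scAvg) / rep((1 + scAvg[, tEDi]), ncol(scAvg)) - 1
    strain <- methods::new("StrainCurveSet", sc = scAvg,
                           globalSc = colMeans(scAvg, na.rm = TRUE),
                           xs = run1$strain@xs, origin = "averaged",
                           tED = tEDi, timeMs = t1)
  }
  maskStrain <- run1$maskStrain
  if (!is.null(run1$maskStrain) && !is.null(run2$maskStrain)) {
    scg2 <- .resamplePeriodic(t2, run2$maskStrain$sc_g, T2, tq)
    maskStrain <- run1$maskStrain
    maskStrain$sc_g <- (run1$maskStrain$sc_g + scg2) / 2
  }
  run <- run1
  run$waveforms <- wf
  run$strain <- strain
  run$maskStrain <- maskStrain
  run$averagedFrom <- c(run1$label %||% "run1", run2$label %||% "run2")
  list(run = run, stretch = bestS, correlation = best)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
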
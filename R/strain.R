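#' @include AllClasses.R
NULL

#' Mean segment trajectories
#'
#' Mean in-plane position, per frame, of the valid trajectories seeded in
#' each segment (segment membership fixed at the origin frame).  A segment
#' left with zero valid trajectories is reported in the `missing` element;
#' strain computed from these curves flags that segment and its two
#' neighbours as missing.
#'
#' @param traj a (filtered) [TrajectorySet-class]
#' @param nSegments number of segments (default 32)
#' @return list with `xs` (array segment x frame x 2, mm) and `missing`
#'   (0-based indices of segments without valid trajectories)
#' @export
segmentPaths <- function(traj, nSegments = 32L) {
  nF <- dim(traj@paths)[2]
  xs <- array(NA_real_, c(nSegments, nF, 2))
  missing <- integer()
  for (s in 0:(nSegments - 1)) {
    sel <- traj@valid & traj@seedSegment == s
    if (!any(sel)) {
      missing <- c(missing, s)
      next
    }
    xs[s + 1, , 1] <- colMeans(traj@paths[sel, , 1, drop = FALSE])
    xs[s + 1, , 2] <- colMeans(traj@paths[sel, , 2, drop = FALSE])
  }
  list(xs = xs, missing = missing)
}

#' Segmental circumferential Lagrangian strain
#'
#' Strain of segment `s` from the chord between the mean trajectories of its
#' two adjacent segments:
#' `Sc_s(t) = |x_{s-1}(t) - x_{s+1}(t)| / |x_{s-1}(t_ED) - x_{s+1}(t_ED)| - 1`
#' with segment indices mod 32.  The reference frame is the end-diastolic
#' frame (the first frame of the trimmed cycle), so `Sc_s(t_ED) = 0` exactly
#' for every segment -- a direct consequence of the closed trajectories.
#' The chord (straight-line) distance is used as written; no arc-length
#' correction is applied.
#'
#' @param seg the list returned by [segmentPaths()]
#' @param tED end-diastolic frame index (strain reference frame)
#' @param frameMs frame spacing (ms)
#' @param origin label stored in the result ("ED" or "ES")
#' @return a [StrainCurveSet-class]; segments adjacent to (or equal to) a
#'   missing segment carry NA
#' @export
circumferentialStrain <- function(seg, tED = 1L, frameMs = 1,
                                  origin = "ED") {
  xs <- seg$xs
  nSeg <- dim(xs)[1]
  nF <- dim(xs)[2]
  scm <- matrix(NA_real_, nSeg, nF)
  for (s in seq_len(nSeg)) {
    sm <- ((s - 2) %% nSeg) + 1
    sp <- (s %% nSeg) + 1
    dx <- xs[sm, , 1] - xs[sp, , 1]
    dy <- xs[sm, , 2] - xs[sp, , 2]
    chord <- sqrt(dx^2 + dy^2)
    if (anyNA(chord)) next
    if (chord[tED] < 1e-9)
      stop("zero baseline chord for segment ", s - 1)
    scm[s, ] <- chord / chord[tED] - 1
  }
  if (length(seg$missing)) {
    for (s0 in seg$missing) {
      scm[((s0 - 1) %% nSeg) + 1, ] <- NA_real_
      scm[(s0 %% nSeg) + 1, ] <- NA_real_
      scm[((s0 + 1) %% nSeg) + 1, ] <- NA_real_
    }
  }
  if (all(is.na(scm)))
    stop("no segment has a complete strain curve")
  methods::new("StrainCurveSet", sc = scm,
               globalSc = colMeans(scm, na.rm = TRUE), xs = xs,
               origin = origin, tED = as.integer(tED),
               timeMs = (seq_len(nF) - 1) * frameMs)
}

#' Average ED- and ES-origin strain curves
#'
#' Element-wise mean, per segment and frame, of the strain waveforms from
#' the two trajectory tracings (end-diastolic and end-systolic temporal
#' origins).  Where one input is flagged missing the other is used; where
#' both are missing the flag propagates.
#'
#' @param scED,scES [StrainCurveSet-class] objects on the same time base
#' @return a [StrainCurveSet-class] with origin `"averaged"`
#' @export
averageDualOrigin <- function(scED, scES) {
  stopifnot(all(dim(scED@sc) == dim(scES@sc)), scED@tED == scES@tED)
  a <- scED@sc; b <- scES@sc
  avg <- (a + b) / 2
  avg[is.na(a) & !is.na(b)] <- b[is.na(a) & !is.na(b)]
  avg[is.na(b) & !is.na(a)] <- a[is.na(b) & !is.na(a)]
  methods::new("StrainCurveSet", sc = avg,
               globalSc = colMeans(avg, na.rm = TRUE), xs = scED@xs,
               origin = "averaged", tED = scED@tED, timeMs = scED@timeMs)
}

#' Polygon-based global circumferential strain
#'
#' Internal-control strain computed directly from the segmentation polygons:
#' `Sc_g(t) = 1/2 [ (L_epi(t) - L_epi(1)) / L_epi(1)
#'               + (L_endo(t) - L_endo(1)) / L_endo(1) ]`
#' where `L_epi`, `L_endo` are the perimeters of the polygons delineating
#' the subepi- and subendocardium and frame 1 is the end-diastolic
#' reference.  On incompressible deformation this mask-derived strain
#' systematically overestimates (in magnitude) the trajectory-derived
#' mid-wall strain, because the endocardial border shortens more than the
#' mid-wall fibres.
#'
#' @param polys per-frame contours: either the `list(epi, endo)` returned by
#'   [interpolateContours()] or a [SegmentModel-class]
#' @param tED reference (end-diastolic) frame index
#' @return a data.frame with columns `frame`, `L_epi_mm`, `L_endo_mm`, `sc_g`
#' @export
maskStrain <- function(polys, tED = 1L) {
  if (methods::is(polys, "SegmentModel")) {
    tED <- polys@tED
    polys <- list(epi = polys@epiPolys, endo = polys@endoPolys)
  }
  lepi <- vapply(polys$epi, .polyPerimeter, numeric(1))
  lendo <- vapply(polys$endo, .polyPerimeter, numeric(1))
  if (any(lepi < 1e-9) || any(lendo < 1e-9))
    stop("degenerate polygon with zero perimeter")
  scg <- 0.5 * ((lepi - lepi[tED]) / lepi[tED] +
                  (lendo - lendo[tED]) / lendo[tED])
  data.frame(frame = seq_along(lepi), L_epi_mm = lepi, L_endo_mm = lendo,
             sc_g = scg)
}
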
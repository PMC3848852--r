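#' @include AllClasses.R
NULL

.sdConv <- function(x, sample = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(0)
  s <- stats::sd(x)
  if (sample) s else s * sqrt((n - 1) / n)
}

#' Dispersion of peak motion
#'
#' Standard deviation over the 32 segments of the regional radial velocities
#' at peak systole (cm/s).  Sample (n-1) convention by default.
#'
#' @param radial a radial [WaveformSet-class]
#' @param key a [KeyTimepoints-class]
#' @param sample use the sample (n-1) standard deviation
#' @return dispersion in cm/s
#' @export
dispersionOfPeakMotion <- function(radial, key, sample = TRUE) {
  .sdConv(radial@regional[, key@tPeakSystole], sample)
}

#' Dispersion of peak strain
#'
#' Segment-wise standard deviation of the regional circumferential strain at
#' end-systole, in %strain.
#'
#' @param strain a [StrainCurveSet-class]
#' @param key a [KeyTimepoints-class]
#' @param sample use the sample (n-1) standard deviation
#' @return dispersion in %strain
#' @export
dispersionOfPeakStrain <- function(strain, key, sample = TRUE) {
  .sdConv(100 * strain@sc[, key@tEndSystole], sample)
}

#' Coherence and dispersion of motion waveforms
#'
#' Pearson correlation of each segment's radial velocity waveform against
#' the global waveform; coherence is the mean and dispersion the standard
#' deviation of the 32 coefficients.  Zero-variance segment waveforms have
#' no defined correlation; they are excluded and reported.
#'
#' @param radial a radial [WaveformSet-class]
#' @param sample use the sample (n-1) standard deviation
#' @return list with `coherence`, `dispersion`, `r` (per-segment
#'   coefficients) and `excluded` (0-based indices of excluded segments)
#' @export
waveformCoherence <- function(radial, sample = TRUE) {
  r <- apply(radial@regional, 1, .safeCor, b = radial@global)
  excluded <- which(is.na(r)) - 1L
  list(coherence = mean(r, na.rm = TRUE),
       dispersion = .sdConv(r, sample),
       r = r, excluded = excluded)
}

# circular cross-correlation delay (in frames, sub-frame refined) of y vs
# reference g, searched within +/- window frames
.xcorrDelay <- function(y, g, window) {
  nF <- length(g)
  lags <- -window:window
  cc <- vapply(lags, function(L) {
    # advance y by L frames: a waveform delayed by d is recovered at L = d
    shifted <- y[((seq_len(nF) - 1 + L) %% nF) + 1]
    r <- .safeCor(shifted, g)
    if (is.na(r)) -Inf else r
  }, numeric(1))
  if (all(!is.finite(cc))) return(NA_real_)
  i <- which.max(cc)
  lag <- lags[i]
  # quadratic interpolation of the correlation peak
  if (i > 1 && i < length(lags) && is.finite(cc[i - 1]) &&
      is.finite(cc[i + 1])) {
    den <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (abs(den) > 1e-12) {
      off <- 0.5 * (cc[i - 1] - cc[i + 1]) / den
      if (abs(off) <= 1) lag <- lag + off
    }
  }
  lag
}

#' Index of dyssynchrony
#'
#' Cross-correlation delay analysis: for each segment, the circular temporal
#' shift of the regional radial velocity waveform that maximizes its
#' correlation with the global waveform (searched within +/- 25 % of the
#' cycle, refined to sub-frame precision by quadratic interpolation of the
#' correlation peak).  The index is the standard deviation of the 32 delays
#' in ms.  Flat (zero-variance) waveforms have no defined delay and are
#' excluded.
#'
#' @param radial a radial [WaveformSet-class]
#' @param windowFrac half-width of the delay search window as a fraction of
#'   the cycle
#' @param sample use the sample (n-1) standard deviation
#' @return list with `indexMs`, `delaysMs` (per segment) and `excluded`
#' @export
dyssynchronyIndex <- function(radial, windowFrac = 0.25, sample = TRUE) {
  nF <- length(radial@global)
  window <- max(1L, floor(windowFrac * nF))
  delays <- apply(radial@regional, 1, .xcorrDelay, g = radial@global,
                  window = window)
  dtMs <- if (length(radial@timeMs) > 1)
    diff(radial@timeMs[1:2]) else 1
  delaysMs <- delays * dtMs
  list(indexMs = .sdConv(delaysMs, sample), delaysMs = delaysMs,
       excluded = which(is.na(delays)) - 1L)
}

#' Resample a cyclic curve for cross-modality comparison
#'
#' Cubic-spline resampling of a full-cycle curve to `nPoints` equally spaced
#' time points (periodic spline).
#'
#' @param y curve values over one cycle (equally spaced)
#' @param nPoints number of output points (default 23)
#' @return numeric vector of length `nPoints`
#' @export
resampleCurve <- function(y, nPoints = 23L) {
  if (nPoints < 4) stop("nPoints must be at least 4")
  nF <- length(y)
  tx <- seq_len(nF) - 1
  f <- .periodicSplineFun(tx, y, nF)
  f(seq(0, nF, length.out = nPoints + 1)[seq_len(nPoints)])
}

#' Synchronize curves to peak global strain
#'
#' Circularly shifts each curve so its extremum (most negative value, the
#' peak global circumferential strain) lands at a common index -- the
#' alignment used before paired comparison of strain curves from different
#' modalities.
#'
#' @param curves list of equal-length numeric vectors
#' @param peakIndex target index for the peak (default: peak of the first
#'   curve)
#' @return list of shifted curves
#' @export
synchronizeToPeak <- function(curves, peakIndex = NULL) {
  if (is.null(peakIndex)) peakIndex <- which.min(curves[[1]])
  lapply(curves, function(y) {
    n <- length(y)
    shift <- which.min(y) - peakIndex
    y[((seq_len(n) - 1 + shift) %% n) + 1]
  })
}

#' Bland-Altman limits of agreement
#'
#' Bias (mean difference) and half-width (1.96 times the SD of the
#' differences) of two paired measurement series, reported as
#' `bias +/- halfWidth`.
#'
#' @param a,b paired numeric vectors
#' @return list with `bias`, `halfWidth`, `n`
#' @export
limitsOfAgreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  if (length(d) < 3) stop("limits of agreement need at least 3 pairs")
  list(bias = mean(d), halfWidth = 1.96 * stats::sd(d), n = length(d))
}

#' Global peak velocities and strain
#'
#' Maximum and minimum of the global radial velocity over the cycle
#' (contraction positive) and the extremum (most negative value) of the
#' global circumferential strain.
#'
#' @param radial a radial [WaveformSet-class]
#' @param strain a [StrainCurveSet-class]
#' @return list with `radialMaxCmS`, `radialMinCmS`, `peakScPercent` and the
#'   frames at which they occur
#' @export
globalPeaks <- function(radial, strain) {
  g <- radial@global
  gs <- strain@globalSc
  list(radialMaxCmS = max(g), radialMinCmS = min(g),
       peakScPercent = 100 * min(gs, na.rm = TRUE),
       tRadialMax = which.max(g), tRadialMin = which.min(g),
       tPeakSc = which.min(gs))
}

#' Regional function indices
#'
#' Computes the five regional indices (and the global peaks) from the
#' processed waveforms and strain of one dataset.
#'
#' @param radial a radial [WaveformSet-class]
#' @param strain a [StrainCurveSet-class]
#' @param key a [KeyTimepoints-class]
#' @param sample use the sample (n-1) standard deviation
#' @return named list: `peakRadialMaxCmS`, `peakRadialMinCmS`,
#'   `peakScPercent`, `dispersionPeakMotionCmS`,
#'   `dispersionPeakStrainPercent`, `coherenceMotion`,
#'   `dispersionMotionWaveforms`, `dyssynchronyIndexMs`
#' @export
regionalIndices <- function(radial, strain, key, sample = TRUE) {
  pk <- globalPeaks(radial, strain)
  coh <- waveformCoherence(radial, sample)
  dys <- dyssynchronyIndex(radial, sample = sample)
  list(peakRadialMaxCmS = pk$radialMaxCmS,
       peakRadialMinCmS = pk$radialMinCmS,
       peakScPercent = pk$peakScPercent,
       dispersionPeakMotionCmS = dispersionOfPeakMotion(radial, key, sample),
       dispersionPeakStrainPercent = dispersionOfPeakStrain(strain, key,
                                                            sample),
       coherenceMotion = coh$coherence,
       dispersionMotionWaveforms = coh$dispersion,
       dyssynchronyIndexMs = dys$indexMs)
}

#' Two-group comparison
#'
#' Convenience Student's t-test wrapper for comparing an index between two
#' groups of datasets (p <= 0.05 conventionally significant).
#'
#' @param a,b numeric vectors of per-dataset index values
#' @param ... passed to [stats::t.test()]
#' @return the `htest` object
#' @export
compareGroups <- function(a, b, ...) {
  stats::t.test(a, b, ...)
}
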
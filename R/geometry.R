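#' @include AllClasses.R
NULL

#' Interpolate contours across the cine
#'
#' Expands key-frame contour annotations to every frame.  Each key polygon is
#' resampled to a fixed vertex count, equally spaced in arc length and
#' anchored where the ray from the polygon centroid towards the papillary
#' reference crosses the boundary, so vertices are materially matched across
#' key frames.  Matched vertices are then linearly interpolated in time;
#' frames outside the key-frame range use periodic extension over the cycle
#' (frame `nFrames + 1` is identified with frame 1).
#'
#' @param contours a [ContourSet-class]
#' @param nFrames number of frames to interpolate to
#' @param nVertices vertex count of the resampled polygons (default 256)
#' @return a list with `epi` and `endo`, each a list of `nFrames` polygon
#'   matrices (mm)
#' @export
interpolateContours <- function(contours, nFrames, nVertices = 256L) {
  methods::validObject(contours)
  key <- contours@keyFrames
  if (length(key) < 2L)
    stop("at least 2 key frames are required")
  ord <- order(key)
  key <- key[ord]
  interpOne <- function(polys) {
    polys <- polys[ord]
    res <- lapply(polys, function(p) {
      ctr <- .polyCentroid(p)
      ang <- atan2(contours@papillary[1, 2] - ctr[2],
                   contours@papillary[1, 1] - ctr[1])
      .resamplePolygon(p, nVertices, ang, ctr)
    })
    # periodic extension: repeat the first key polygon one cycle later
    keyExt <- c(key, key[1] + nFrames)
    resExt <- c(res, res[1])
    out <- vector("list", nFrames)
    for (f in seq_len(nFrames)) {
      fq <- f
      if (fq < keyExt[1]) fq <- fq + nFrames
      i <- findInterval(fq, keyExt)
      i <- min(max(i, 1L), length(keyExt) - 1L)
      span <- keyExt[i + 1] - keyExt[i]
      w <- if (span == 0) 0 else (fq - keyExt[i]) / span
      out[[f]] <- (1 - w) * resExt[[i]] + w * resExt[[i + 1]]
    }
    out
  }
  list(epi = interpOne(contours@epi), endo = interpOne(contours@endo))
}

#' Build the per-frame segment model
#'
#' Rasterizes the interpolated contours into a per-frame myocardial mask
#' (pixel centres inside the epicardial and outside the endocardial polygon)
#' and assigns every masked pixel to one of `nSegments` angular segments,
#' `floor(nSegments * dTheta / 2 pi)`, where `dTheta` is the pixel's angle
#' relative to the papillary reference angle counted in the anatomical
#' direction (counter-clockwise as displayed, by default).  The LV centre is
#' the epicardial polygon centroid per frame, so mask and segments follow the
#' LV through the cycle.  Fold-over regions and wrap-flagged pixels are
#' removed from the mask.
#'
#' @param polys the list returned by [interpolateContours()]
#' @param contours the [ContourSet-class] (papillary landmarks, fold-over
#'   regions, end-diastolic frame)
#' @param gridSize image matrix size (pixels)
#' @param pixelMm pixel size (mm)
#' @param nSegments number of angular segments (default 32)
#' @param direction segment counting direction; `"ccw"` is counter-clockwise
#'   in the displayed image
#' @param wrapped optional logical (frame, y, x) array of wrap-flagged pixels
#' @return a [SegmentModel-class]
#' @export
buildSegmentModel <- function(polys, contours, gridSize, pixelMm,
                              nSegments = 32L, direction = c("ccw", "cw"),
                              wrapped = NULL) {
  direction <- match.arg(direction)
  nF <- length(polys$epi)
  n <- gridSize
  co <- .pixelCoords(n, pixelMm)
  px <- rep(co, each = n)   # x across columns, column-major (y, x)
  py <- rep(co, times = n)
  excl <- rep(FALSE, n * n)
  for (p in contours@foldover) excl <- excl | .inPoly(px, py, p)
  mask <- array(FALSE, c(nF, n, n))
  segMap <- array(NA_integer_, c(nF, n, n))
  center <- matrix(0, nF, 2)
  refAngle <- numeric(nF)
  for (f in seq_len(nF)) {
    inEpi <- .inPoly(px, py, polys$epi[[f]])
    inEndo <- .inPoly(px, py, polys$endo[[f]])
    m <- inEpi & !inEndo & !excl
    if (!is.null(wrapped)) m <- m & !c(wrapped[f, , ])
    if (!any(m)) stop("empty myocardial mask at frame ", f)
    ctr <- .polyCentroid(polys$epi[[f]])
    ref <- atan2(contours@papillary[1, 2] - ctr[2],
                 contours@papillary[1, 1] - ctr[1])
    th <- atan2(py[m] - ctr[2], px[m] - ctr[1])
    seg <- .segmentIndex(th, ref, nSegments, direction)
    mk <- matrix(FALSE, n, n); mk[m] <- TRUE
    sg <- matrix(NA_integer_, n, n); sg[m] <- seg
    mask[f, , ] <- mk
    segMap[f, , ] <- sg
    center[f, ] <- ctr
    refAngle[f] <- ref
  }
  methods::new("SegmentModel", mask = mask, segmentMap = segMap,
               center = center, refAngle = refAngle,
               nSegments = as.integer(nSegments), direction = direction,
               pixelMm = pixelMm, epiPolys = polys$epi,
               endoPolys = polys$endo, tED = contours@tLastDiastole)
}

#' Per-frame LV lumen area
#'
#' Area (mm^2) of the endocardial polygon at every frame; the minimum over
#' the cycle defines end-systole.
#'
#' @param model a [SegmentModel-class]
#' @return numeric vector of areas (mm^2)
#' @export
lumenArea <- function(model) {
  vapply(model@endoPolys, .polyArea, numeric(1))
}
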
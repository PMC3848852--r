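# Internal geometry / waveform helpers shared across modules.

# velocity in cm/s times frame spacing in ms gives displacement in mm after
# multiplying by this factor (1 cm/s = 0.01 mm/ms)
.CMS_TO_MM_PER_MS <- 0.01

#' Pixel-centre physical coordinates
#'
#' Mm coordinate of each pixel centre along one image axis.  The convention
#' used throughout the package: 0-based pixel index `i` maps to
#' `(i - (N - 1) / 2) * pixel_mm`, x increases with column, y with row.
#'
#' @param n number of pixels along the axis
#' @param pixelMm pixel size in mm
#' @return numeric vector of length `n`
#' @keywords internal
.pixelCoords <- function(n, pixelMm) {
  (seq_len(n) - 1 - (n - 1) / 2) * pixelMm
}

# nearest pixel index (1-based) for a physical mm coordinate; NA outside FOV
.coordToIndex <- function(x, n, pixelMm) {
  i <- round(x / pixelMm + (n - 1) / 2) + 1
  i[i < 1 | i > n] <- NA_integer_
  as.integer(i)
}

.mod2pi <- function(a) a %% (2 * pi)

# signed area via the shoelace formula (positive for counter-clockwise in
# standard math orientation); `poly` is an n x 2 matrix of vertices
.polyArea <- function(poly) {
  abs(pracma::polyarea(poly[, 1], poly[, 2]))
}

.polyPerimeter <- function(poly) {
  d <- diff(rbind(poly, poly[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# area centroid of a simple polygon
.polyCentroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# points-in-polygon test; px, py numeric vectors, poly n x 2 matrix
.inPoly <- function(px, py, poly) {
  if (nrow(poly) < 3) return(rep(FALSE, length(px)))
  mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
               cbind(as.numeric(px), as.numeric(py)))
}

# union membership over a list of polygons
.inAnyPoly <- function(px, py, polys) {
  out <- rep(FALSE, length(px))
  for (p in polys) out <- out | .inPoly(px, py, p)
  out
}

# Resample a closed polygon to `n` vertices, equally spaced in arc length,
# with the first vertex anchored where the ray from `center` at `anchorAngle`
# crosses the boundary.  Used so that vertices of different key frames are
# materially matched before linear interpolation.  The original traversal
# orientation (cw or ccw) is preserved.
.resamplePolygon <- function(poly, n, anchorAngle, center = NULL) {
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  if (is.null(center)) center <- .polyCentroid(poly)
  hit <- .rayBoundaryIntersection(poly, center, anchorAngle)
  m <- nrow(poly)
  # walk the boundary from the intersection point, following the polygon's
  # own vertex order starting with the endpoint of the intersected edge
  after <- if (hit$edge < m) (hit$edge + 1):m else integer()
  path <- rbind(hit$point, poly[after, , drop = FALSE],
                poly[seq_len(hit$edge), , drop = FALSE], hit$point)
  seglen <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  keep <- c(TRUE, seglen > 1e-12)   # drop duplicated points
  path <- path[keep, , drop = FALSE]
  s <- s[keep]
  target <- seq(0, total, length.out = n + 1)[seq_len(n)]
  cbind(stats::approx(s, path[, 1], xout = target, rule = 2)$y,
        stats::approx(s, path[, 2], xout = target, rule = 2)$y)
}

# first intersection of the ray from `center` at angle `ang` with the
# polygon boundary; returns the point and the index i of the intersected
# edge poly[i] -> poly[i + 1 (cyclic)]
.rayBoundaryIntersection <- function(poly, center, ang) {
  d <- c(cos(ang), sin(ang))
  a <- sweep(poly, 2, center)
  b <- sweep(rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]),
             2, center)
  best <- Inf; hit <- NULL; edge <- NA_integer_
  for (i in seq_len(nrow(a))) {
    e <- b[i, ] - a[i, ]
    den <- d[1] * (-e[2]) - d[2] * (-e[1])
    if (abs(den) < 1e-14) next
    tt <- (a[i, 1] * (-e[2]) - a[i, 2] * (-e[1])) / den
    uu <- (d[1] * a[i, 2] - d[2] * a[i, 1]) / den
    if (tt > 0 && uu >= -1e-12 && uu <= 1 + 1e-12 && tt < best) {
      best <- tt
      hit <- center + tt * d
      edge <- i
    }
  }
  if (is.null(hit)) stop("anchor ray does not intersect polygon boundary")
  list(point = hit, edge = edge)
}

# 2x2 rotation matrix, angle in radians, standard math orientation
.rotMat <- function(ang) {
  matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
}

# Raised-cosine systolic activation pulse occupying the first `frac` of the
# cycle: smooth, periodic, zero-valued and zero-slope at cycle boundaries.
.activationPulse <- function(t, periodMs, frac = 0.4) {
  tau <- (t %% periodMs) / (frac * periodMs)
  ifelse(tau < 1, 0.5 * (1 - cos(2 * pi * tau)), 0)
}

.activationPulseDot <- function(t, periodMs, frac = 0.4) {
  tau <- (t %% periodMs) / (frac * periodMs)
  ifelse(tau < 1, (pi / (frac * periodMs)) * sin(2 * pi * tau), 0)
}

# Continuous segment coordinate u in [0, nSeg) of angles `theta` relative to
# the papillary reference angle, counted in the configured direction
# ("ccw" = counter-clockwise as displayed with the y axis pointing down).
.segmentCoordinate <- function(theta, refAngle, nSeg = 32L,
                               direction = c("ccw", "cw")) {
  direction <- match.arg(direction)
  delta <- if (direction == "ccw") refAngle - theta else theta - refAngle
  .mod2pi(delta) * nSeg / (2 * pi)
}

# inverse: angle of the centre of segment s (0-based)
.segmentCenterAngle <- function(s, refAngle, nSeg = 32L,
                                direction = c("ccw", "cw")) {
  direction <- match.arg(direction)
  u <- (s + 0.5) * 2 * pi / nSeg
  if (direction == "ccw") refAngle - u else refAngle + u
}

# segment index of angles (0-based), boundary ties going to the lower index
.segmentIndex <- function(theta, refAngle, nSeg = 32L, direction = "ccw") {
  u <- .segmentCoordinate(theta, refAngle, nSeg, direction)
  s <- floor(u)
  tie <- (u == s) & (u > 0)
  s[tie] <- s[tie] - 1
  as.integer(s %% nSeg)
}

# Evaluate a per-segment piecewise-constant field at angles `theta`, blended
# with a raised-cosine ramp over `blendDeg` degrees across segment boundaries
# so that derived velocity fields stay continuous.
.segmentField <- function(theta, values, refAngle, nSeg = 32L,
                          direction = "ccw", blendDeg = 5) {
  u <- .segmentCoordinate(theta, refAngle, nSeg, direction)
  s <- pmin(floor(u), nSeg - 1)
  f <- u - s
  half <- (blendDeg / (360 / nSeg)) / 2
  v <- values[(s %% nSeg) + 1]
  if (half > 0) {
    lo <- f < half
    if (any(lo)) {
      q <- 0.5 * (1 + sin(pi * f[lo] / (2 * half)))
      prev <- values[((s[lo] - 1) %% nSeg) + 1]
      v[lo] <- (1 - q) * prev + q * values[(s[lo] %% nSeg) + 1]
    }
    hi <- f > 1 - half
    if (any(hi)) {
      q <- 0.5 * (1 + sin(pi * (f[hi] - 1) / (2 * half)))
      nxt <- values[((s[hi] + 1) %% nSeg) + 1]
      v[hi] <- (1 - q) * values[(s[hi] %% nSeg) + 1] + q * nxt
    }
  }
  v
}

# Pearson correlation that returns NA (instead of an error) for
# zero-variance input
.safeCor <- function(a, b) {
  if (stats::sd(a) < 1e-300 || stats::sd(b) < 1e-300) return(NA_real_)
  stats::cor(a, b)
}

# circular (periodic) cubic spline evaluation of a cyclic waveform sampled
# at frame times `tx` (cycle period = length(tx) * dt)
.periodicSplineFun <- function(tx, y, periodMs) {
  stats::splinefun(c(tx, tx[1] + periodMs), c(y, y[1]), method = "periodic")
}
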
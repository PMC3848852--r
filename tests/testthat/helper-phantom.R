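# Shared fixtures: small phantoms, cached default-geometry runs, and
# independent oracles used across test files.

smallSpec <- function(...) {
  defaults <- list(gridSize = 48L, nFrames = 16L, nCoils = 2L, seed = 3L)
  args <- list(...)
  do.call(phantomSpec, c(args, defaults[setdiff(names(defaults),
                                                names(args))]))
}

# memoized heavy fixtures (computed once per test session)
.fixtures <- new.env(parent = emptyenv())
cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

defaultTruth <- function() {
  cachedFixture("truth", makeMotionModel(phantomSpec()))
}

# full default-geometry pipeline run from the rendered velocity cine
defaultRun <- function() {
  cachedFixture("run", {
    truth <- defaultTruth()
    processAcquisition(renderVelocityCine(truth), phantomAnnotations(truth))
  })
}

runForSpec <- function(spec) {
  truth <- makeMotionModel(spec)
  processAcquisition(renderVelocityCine(truth), phantomAnnotations(truth))
}

defaultModel <- function() {
  cachedFixture("model", {
    truth <- defaultTruth()
    ann <- phantomAnnotations(truth)
    polys <- interpolateContours(ann, truth@spec@nFrames)
    buildSegmentModel(polys, ann, truth@spec@gridSize,
                      truth@spec@fovMm / truth@spec@gridSize)
  })
}

# independent RK4 integrator of the analytic velocity field at a `sub`-fold
# finer timestep than the frame spacing; returns (seed, frame, 2) positions
rk4Paths <- function(seeds, truth, nF, dtMs, sub = 10L) {
  pos <- seeds
  out <- array(NA_real_, c(nrow(seeds), nF, 2))
  out[, 1, ] <- pos
  h <- dtMs / sub
  t <- 0
  f <- function(p, t) truth@velocityFn(p[, 1], p[, 2], t)[, 1:2] * 0.01
  for (k in seq_len((nF - 1) * sub)) {
    k1 <- f(pos, t)
    k2 <- f(pos + h / 2 * k1, t + h / 2)
    k3 <- f(pos + h / 2 * k2, t + h / 2)
    k4 <- f(pos + h * k3, t + h)
    pos <- pos + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    if (k %% sub == 0) out[, k / sub + 1, ] <- pos
  }
  out
}

# independent integer-lag circular cross-correlation delay estimate
circularDelayFrames <- function(y, g, maxLag = floor(length(g) / 4)) {
  nF <- length(g)
  lags <- -maxLag:maxLag
  cc <- vapply(lags, function(L) {
    stats::cor(y[((seq_len(nF) - 1 + L) %% nF) + 1], g)
  }, numeric(1))
  lags[which.max(cc)]
}

# build a WaveformSet from a regional matrix (for metric unit tests)
mkWaveforms <- function(regional, global = colMeans(regional), dtMs = 3.2,
                        component = "radial") {
  methods::new("WaveformSet", global = global, regional = regional,
               component = component,
               timeMs = (seq_len(ncol(regional)) - 1) * dtMs,
               imputed = matrix(FALSE, nrow(regional), ncol(regional)))
}

# build a StrainCurveSet directly from a strain matrix (fraction units)
mkStrainSet <- function(scm, tED = 1L, dtMs = 3.2) {
  methods::new("StrainCurveSet", sc = scm,
               globalSc = colMeans(scm, na.rm = TRUE),
               xs = array(0, c(nrow(scm), ncol(scm), 2)), origin = "ED",
               tED = tED, timeMs = (seq_len(ncol(scm)) - 1) * dtMs)
}

# minimal single/multi-frame SegmentModel over a full square grid, centred
# at the origin (for cardiopolar / waveform unit tests)
mkGridModel <- function(n, pixelMm, nFrames = 1L, nSegments = 32L,
                        segmentMap = NULL) {
  mask <- array(TRUE, c(nFrames, n, n))
  if (is.null(segmentMap)) {
    co <- (seq_len(n) - 1 - (n - 1) / 2) * pixelMm
    px <- rep(co, each = n)
    py <- rep(co, times = n)
    th <- atan2(py, px)
    seg <- as.integer(floor(((-th) %% (2 * pi)) * nSegments / (2 * pi)))
    seg[seg >= nSegments] <- nSegments - 1L
    segmentMap <- array(rep(seg, each = nFrames), c(nFrames, n, n))
  }
  half <- n * pixelMm / 2
  sq <- cbind(c(-half, half, half, -half), c(-half, -half, half, half))
  inner <- sq * 1e-3
  methods::new("SegmentModel", mask = mask, segmentMap = segmentMap,
               center = matrix(0, nFrames, 2), refAngle = rep(0, nFrames),
               nSegments = as.integer(nSegments), direction = "ccw",
               pixelMm = pixelMm,
               epiPolys = rep(list(sq), nFrames),
               endoPolys = rep(list(inner), nFrames), tED = 1L)
}

# uniform-velocity cine (velocity in cm/s constant over space per frame)
mkUniformCine <- function(vPerFrame, n = 16L, pixelMm = 1, frameMs = 3.2,
                          vencCmS = 13.9) {
  nF <- nrow(vPerFrame)
  vel <- array(0, c(nF, n, n, 3))
  for (f in seq_len(nF)) for (k in 1:3) vel[f, , , k] <- vPerFrame[f, k]
  methods::new("VelocityCine", velocity = vel,
               magnitude = array(1, c(nF, n, n)),
               wrapped = array(FALSE, c(nF, n, n)), vencCmS = vencCmS,
               frameMs = frameMs, pixelMm = pixelMm,
               nFramesCycle = as.integer(nF))
}
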
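#' @include AllClasses.R
NULL

#' Create a phantom specification
#'
#' Constructor for [PhantomSpec-class] with defaults matching the targeted
#' acquisition: 128 x 128 matrix, 50 x 50 mm FOV, 70 frames at 3.2 ms,
#' venc 13.9 cm/s.  The annulus has end-diastolic radii 3 mm (endo) and 5 mm
#' (epi) -- a rat mid-ventricular LV -- and contracts incompressibly with a
#' peak mid-wall fractional shortening of 0.19 (mid-wall circumferential
#' strain -19 %strain at peak), with a small superposed rigid twist and a
#' uniform through-plane velocity.
#'
#' @param gridSize,fovMm,nFrames,frameMs,vencCmS acquisition geometry/timing
#' @param rEndoMm,rEpiMm end-diastolic annulus radii (mm)
#' @param contractionAmplitude peak fractional shortening of the mid-wall
#'   radius in `[0, 1)`
#' @param rotationAmplitudeRad peak rigid twist (rad)
#' @param longitudinalAmplitudeCmS peak through-plane velocity (cm/s)
#' @param systoleFraction fraction of the cycle occupied by the systolic
#'   raised-cosine activation pulse
#' @param segmentDelaysMs length-32 activation delays (ms)
#' @param hypokinesiaMask length-32 amplitude scalings in `[0, 1]`
#'   (1 = normal, 0 = akinetic)
#' @param driftCmS length-2 spurious uniform in-plane velocity offset (cm/s)
#' @param ghostAmplitude relative intensity of the phase-encode ghost
#' @param fovRotationDeg in-plane rotation of the second acquisition (deg)
#' @param nCoils simulated receive channels
#' @param papillaryAngleRad anterior papillary landmark angle at ED (rad)
#' @param seed random seed for coil sensitivities and ghost realizations
#' @return a validated [PhantomSpec-class]
#' @examples
#' spec <- phantomSpec(gridSize = 64, nFrames = 20)
#' truth <- makeMotionModel(spec)
#' @export
phantomSpec <- function(gridSize = 128L, fovMm = 50, nFrames = 70L,
                        frameMs = 3.2, vencCmS = 13.9,
                        rEndoMm = 3, rEpiMm = 5,
                        contractionAmplitude = 0.19,
                        rotationAmplitudeRad = 0.10,
                        longitudinalAmplitudeCmS = 2,
                        systoleFraction = 0.4,
                        segmentDelaysMs = rep(0, 32),
                        hypokinesiaMask = rep(1, 32),
                        driftCmS = c(0, 0),
                        ghostAmplitude = 0,
                        fovRotationDeg = 30,
                        nCoils = 4L,
                        papillaryAngleRad = 0,
                        seed = 1L) {
  methods::new("PhantomSpec",
    gridSize = as.integer(gridSize), fovMm = fovMm,
    nFrames = as.integer(nFrames), frameMs = frameMs, vencCmS = vencCmS,
    rEndoMm = rEndoMm, rEpiMm = rEpiMm,
    contractionAmplitude = contractionAmplitude,
    rotationAmplitudeRad = rotationAmplitudeRad,
    longitudinalAmplitudeCmS = longitudinalAmplitudeCmS,
    systoleFraction = systoleFraction,
    segmentDelaysMs = segmentDelaysMs, hypokinesiaMask = hypokinesiaMask,
    driftCmS = driftCmS, ghostAmplitude = ghostAmplitude,
    fovRotationDeg = fovRotationDeg, nCoils = as.integer(nCoils),
    papillaryAngleRad = papillaryAngleRad, seed = as.integer(seed))
}

#' Infarct-like phantom specification
#'
#' Convenience wrapper emulating a regionally dysfunctional ventricle:
#' a contiguous block of segments gets its activation amplitude scaled down
#' (hypokinesia) and its activation delayed, producing reduced strain,
#' increased regional dispersion and increased dyssynchrony relative to the
#' default phantom.  The hypokinesia model is a synthetic stand-in, not a
#' mechanical model of post-infarction myocardium.
#'
#' @param segments 0-based indices of the affected segments
#' @param amplitude residual activation amplitude of the affected segments
#' @param delayMs activation delay (ms) of the affected segments
#' @param ... passed to [phantomSpec()]
#' @return a [PhantomSpec-class]
#' @export
infarctPhantomSpec <- function(segments = 8:15, amplitude = 0.25,
                               delayMs = 12, ...) {
  hypo <- rep(1, 32); hypo[segments + 1] <- amplitude
  del <- rep(0, 32); del[segments + 1] <- delayMs
  phantomSpec(hypokinesiaMask = hypo, segmentDelaysMs = del, ...)
}

#' Build the analytic motion model
#'
#' Constructs the closed-form ground truth of the deforming annulus.  The
#' radial mapping is area-preserving, `r(r0, t) = sqrt(r0^2 - a(theta0, t))`,
#' with `a` a raised-cosine systolic activation scaled per 32 end-diastolic
#' angular sectors (hypokinesia) and shifted per sector (activation delays),
#' blended over 5 degrees across sector boundaries so the velocity field is
#' continuous.  A rigid rotation `theta(t) = theta0 + phi(t)` and a spatially
#' uniform through-plane velocity are superposed.  The velocity field is the
#' exact time derivative of the mapping, and the strain function the exact
#' circumferential stretch minus one at the mid-wall radius.
#'
#' The ground truth describes tissue motion only; the `driftCmS`
#' background-velocity offset of the spec is an acquisition-level artifact
#' and is added by [renderVelocityCine()], not here.
#'
#' @param spec a [PhantomSpec-class]
#' @return a [GroundTruth-class]
#' @export
makeMotionModel <- function(spec) {
  methods::validObject(spec)
  Tms <- spec@nFrames * spec@frameMs
  frac <- spec@systoleFraction
  rMid <- (spec@rEndoMm + spec@rEpiMm) / 2
  cAmp <- spec@contractionAmplitude
  aPeak <- rMid^2 * (1 - (1 - cAmp)^2)
  ref <- spec@papillaryAngleRad
  hypo <- spec@hypokinesiaMask
  delays <- spec@segmentDelaysMs

  if (aPeak * max(hypo) >= spec@rEndoMm^2)
    stop("annulus collapse: activation amplitude exceeds the endocardial ",
         "radius squared")

  hFun <- function(th0) .segmentField(th0, hypo, ref)
  dFun <- function(th0) .segmentField(th0, delays, ref)
  aFun <- function(th0, t) {
    aPeak * hFun(th0) * .activationPulse(t - dFun(th0), Tms, frac)
  }
  aDotFun <- function(th0, t) {
    aPeak * hFun(th0) * .activationPulseDot(t - dFun(th0), Tms, frac)
  }
  phiFun <- function(t) {
    spec@rotationAmplitudeRad * .activationPulse(t, Tms, frac)
  }
  phiDotFun <- function(t) {
    spec@rotationAmplitudeRad * .activationPulseDot(t, Tms, frac)
  }
  vzFun <- function(t) spec@longitudinalAmplitudeCmS * sin(2 * pi * t / Tms)
  rEndo2 <- spec@rEndoMm^2
  rEpi2 <- spec@rEpiMm^2

  insideFn <- function(x, y, t) {
    r2 <- x^2 + y^2
    th0 <- atan2(y, x) - phiFun(t)
    r0sq <- r2 + aFun(th0, t)
    r2 > 0 & r0sq >= rEndo2 - 1e-12 & r0sq <= rEpi2 + 1e-12
  }

  velocityFn <- function(x, y, t) {
    r <- sqrt(x^2 + y^2)
    th <- atan2(y, x)
    th0 <- th - phiFun(t)
    a <- aFun(th0, t)
    r0sq <- r^2 + a
    inside <- r > 0 & r0sq >= rEndo2 - 1e-12 & r0sq <= rEpi2 + 1e-12
    drdt <- ifelse(r > 0, -aDotFun(th0, t) / (2 * r), 0)  # mm/ms
    om <- phiDotFun(t)                                    # rad/ms
    vx <- (drdt * cos(th) - r * om * sin(th)) / .CMS_TO_MM_PER_MS
    vy <- (drdt * sin(th) + r * om * cos(th)) / .CMS_TO_MM_PER_MS
    out <- cbind(vx, vy, rep(vzFun(t), length(r)))
    out[!inside, ] <- 0
    unname(out)
  }

  displacementFn <- function(x0, t) {
    x0 <- rbind(x0)
    r0 <- sqrt(x0[, 1]^2 + x0[, 2]^2)
    th0 <- atan2(x0[, 2], x0[, 1])
    rsq <- r0^2 - aFun(th0, t)
    if (any(rsq < 0))
      stop("material point maps inside the collapsed lumen")
    r <- sqrt(rsq)
    th <- th0 + phiFun(t)
    unname(cbind(r * cos(th), r * sin(th)))
  }

  strainFn <- function(s, t) {
    n <- max(length(s), length(t))
    s <- rep_len(s, n); t <- rep_len(t, n)
    th0 <- .segmentCenterAngle(s, ref)
    sqrt(rMid^2 - aFun(th0, t)) / rMid - 1
  }

  contoursFn <- function(t, n = 256L) {
    th0 <- ref - (seq_len(n) - 1) * 2 * pi / n
    phi <- phiFun(t)
    a <- aFun(th0, t)
    mk <- function(r0sq) {
      r <- sqrt(r0sq - a)
      cbind(r * cos(th0 + phi), r * sin(th0 + phi))
    }
    list(epi = mk(rEpi2), endo = mk(rEndo2))
  }

  methods::new("GroundTruth", velocityFn = velocityFn,
               displacementFn = displacementFn, strainFn = strainFn,
               contoursFn = contoursFn, annulusFn = insideFn,
               refAngle = ref, spec = spec)
}

# Square static-tissue patches (chest-wall-like) in anatomical mm
# coordinates, used both for rendering and as static-region annotations.
# Eight patches ring the heart at 45-degree spacing near the FOV edge, so
# the half-FOV phase-encode ghost of the annulus lands on *different*
# patches in differently rotated acquisitions -- each acquisition's
# eddy-current fit then sees its own geometrically systematic artifact.
.staticPatches <- function(spec) {
  ang <- (0:7) * pi / 4
  centers <- cbind(21 * cos(ang), 21 * sin(ang))
  half <- 3.5
  lapply(seq_len(nrow(centers)), function(i) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    cbind(cx + c(-half, half, half, -half), cy + c(-half, -half, half, half))
  })
}

#' Sample the analytic phantom onto a velocity cine
#'
#' Evaluates the ground-truth velocity field at the pixel centres of every
#' frame.  Pixels outside the annulus carry zero velocity; the magnitude
#' image delineates the tissue classes (myocardium 1.0, static chest-wall
#' patches 0.6, black-blood lumen 0.05, air 0.02).  A nonzero `rotationDeg`
#' renders the same anatomy with the field of view rotated in-plane (the
#' second acquisition of a rotating-FOV protocol): grid positions are rotated
#' into the anatomical frame and the in-plane velocity components back into
#' the acquisition frame.
#'
#' @param truth a [GroundTruth-class]
#' @param rotationDeg in-plane FOV rotation of this acquisition (deg)
#' @return a [VelocityCine-class]
#' @export
renderVelocityCine <- function(truth, rotationDeg = 0) {
  spec <- truth@spec
  n <- spec@gridSize
  px <- spec@fovMm / n
  co <- .pixelCoords(n, px)
  g <- expand.grid(y = co, x = co)  # y fastest: column-major (y, x)
  beta <- rotationDeg * pi / 180
  Rf <- .rotMat(beta)               # image -> anatomy
  Rb <- .rotMat(-beta)              # anatomy -> image
  pa <- cbind(g$x, g$y) %*% t(Rf)
  xa <- pa[, 1]; ya <- pa[, 2]
  nF <- spec@nFrames
  vel <- array(0, c(nF, n, n, 3))
  mag <- array(0.02, c(nF, n, n))
  statics <- .staticPatches(spec)
  inStatic <- rep(FALSE, length(xa))
  for (p in statics) inStatic <- inStatic | .inPoly(xa, ya, p)
  rEndo2 <- spec@rEndoMm^2
  for (f in seq_len(nF)) {
    t <- (f - 1) * spec@frameMs
    v <- truth@velocityFn(xa, ya, t)
    vIm <- cbind(v[, 1:2] %*% t(Rb), v[, 3])
    myo <- truth@annulusFn(xa, ya, t)
    vIm[!myo, 1:2] <- 0
    # driftCmS emulates a residual background-phase error: a spatially
    # uniform in-plane velocity offset over the whole FOV, removed exactly
    # by bulk-motion subtraction downstream
    vel[f, , , 1] <- vIm[, 1] + spec@driftCmS[1]
    vel[f, , , 2] <- vIm[, 2] + spec@driftCmS[2]
    vel[f, , , 3] <- ifelse(myo, vIm[, 3], 0)
    # lumen: inside the (possibly contracted) endocardial border
    lum <- !myo & (xa^2 + ya^2) < rEndo2
    m <- rep(0.02, length(xa))
    m[inStatic] <- 0.6
    m[lum] <- 0.05
    m[myo] <- 1.0
    mag[f, , ] <- m
  }
  methods::new("VelocityCine", velocity = vel, magnitude = mag,
               wrapped = array(FALSE, c(nF, n, n)), vencCmS = spec@vencCmS,
               frameMs = spec@frameMs, pixelMm = px,
               nFramesCycle = as.integer(nF))
}

#' Nine-point balanced encoding moment matrix
#'
#' The default gradient first-moment matrix: a zero reference row plus the
#' eight corners of a symmetric cube `(+/-1, +/-1, +/-1)/sqrt(3)`, i.e. a
#' balanced set of unit-norm encoding directions spanning 3D.  Rows are
#' normalized so that a velocity of venc along a unit-moment row gives a
#' phase of pi.
#'
#' @return a 9 x 3 numeric matrix
#' @export
ninePointMoments <- function() {
  s <- 1 / sqrt(3)
  corners <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1),
                                   z = c(-1, 1))) * s
  rbind(c(0, 0, 0), unname(corners))
}

# deterministic smooth complex coil sensitivity maps (low-order polynomial
# magnitude, linear phase), one (ny x nx) complex matrix per coil
.coilSensitivities <- function(n, nCoils, seed) {
  co <- .pixelCoords(n, 2 / n)  # normalized [-1, 1] coords
  u <- matrix(co, n, n, byrow = TRUE)  # x across columns
  v <- matrix(co, n, n)                # y down rows
  rng <- .seededRNG(seed)
  lapply(seq_len(nCoils), function(k) {
    cc <- rng(7)
    magn <- 0.7 + 0.25 * (cc[1] * u + cc[2] * v) +
      0.15 * cc[3] * u * v + 0.1 * cc[4] * (u^2 - v^2)
    magn <- pmax(magn, 0.1)
    ph <- pi * (cc[5] + 0.5 * cc[6] * u + 0.5 * cc[7] * v)
    magn * exp(1i * ph)
  })
}

# local RNG (uniform in [-1, 1]) that does not disturb the global .Random.seed
.seededRNG <- function(seed) {
  rs <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  state <- get(".Random.seed", globalenv())
  if (!is.null(rs)) assign(".Random.seed", rs, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  function(m) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    assign(".Random.seed", state, globalenv())
    out <- stats::runif(m, -1, 1)
    state <<- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    out
  }
}

#' Simulate a velocity-encoded multi-coil acquisition
#'
#' Forward-models the nine-point encoding: for each encoding row `M_e` the
#' complex signal phase equals `(pi / venc) * (M_e . v)`, replicated over
#' `nCoils` receive channels with smooth deterministic coil sensitivities.
#' Optionally adds (a) per-encoding linear background-phase ramps (an
#' eddy-current surrogate for exercising the phase correction), and (b) a
#' phase-encode ghost: a single replica of the bright moving-tissue signal,
#' circularly shifted by half the FOV along the phase-encode (row) axis and
#' scaled by `ghostAmplitude`, with an independent complex gain per encoding
#' point drawn from `seed + acqIndex` so repeated acquisitions get
#' independent artifact realizations.
#'
#' Velocities exceeding venc along an encoding direction produce wrapped
#' phases; a warning is emitted and the wrap is left in the data so that
#' downstream wrap flagging can be exercised.
#'
#' @param cine a [VelocityCine-class]
#' @param spec the generating [PhantomSpec-class] (supplies venc, coils,
#'   ghost amplitude and seed)
#' @param moments 9 x 3 encoding first-moment matrix
#' @param rotationDeg FOV rotation recorded in the container (deg)
#' @param acqIndex 1-based acquisition counter (ghost realization selector)
#' @param eddyRampsRad optional 9 x 3 matrix of per-encoding phase ramps
#'   `(gx, gy, g0)` in radians: `gx`/`gy` across the half-FOV, `g0` constant
#' @return an [EncodedAcquisition-class]
#' @export
encodeAcquisition <- function(cine, spec, moments = ninePointMoments(),
                              rotationDeg = 0, acqIndex = 1L,
                              eddyRampsRad = NULL) {
  n <- dim(cine@velocity)[2]
  nF <- dim(cine@velocity)[1]
  nCoils <- spec@nCoils
  vencV <- cine@vencCmS
  vx <- cine@velocity[, , , 1]
  vy <- cine@velocity[, , , 2]
  vz <- cine@velocity[, , , 3]
  peak <- max(abs(cbind(c(vx), c(vy), c(vz)) %*% t(moments)))
  if (peak >= vencV)
    warning("velocity exceeds venc along an encoding direction; ",
            "phase will wrap")
  sens <- .coilSensitivities(n, nCoils, spec@seed)
  co <- .pixelCoords(n, 2 / n)
  uu <- matrix(co, n, n, byrow = TRUE)
  vvn <- matrix(co, n, n)
  moving <- cine@magnitude > 0.9
  shift <- ((seq_len(n) - 1 + n %/% 2) %% n) + 1
  rng <- .seededRNG(spec@seed + 1000L * as.integer(acqIndex))
  gphase <- pi * rng(9)
  arr <- array(complex(real = 0), c(9, nF, n, n, nCoils))
  for (e in seq_len(9)) {
    m <- moments[e, ]
    ph <- (pi / vencV) * (m[1] * vx + m[2] * vy + m[3] * vz)
    if (!is.null(eddyRampsRad)) {
      ramp <- eddyRampsRad[e, 1] * uu + eddyRampsRad[e, 2] * vvn +
        eddyRampsRad[e, 3]
      ph <- ph + rep(ramp, each = nF)
    }
    enc <- exp(1i * ph)
    for (k in seq_len(nCoils)) {
      s0 <- cine@magnitude * rep(sens[[k]], each = nF)
      se <- s0 * enc
      if (spec@ghostAmplitude > 0) {
        src <- se
        src[!moving] <- 0
        dim(src) <- c(nF, n, n)
        se <- se + spec@ghostAmplitude * exp(1i * gphase[e]) *
          src[, shift, , drop = FALSE]
      }
      arr[e, , , , k] <- se
    }
  }
  methods::new("EncodedAcquisition", data = arr, moments = moments,
               vencCmS = vencV, frameMs = cine@frameMs,
               pixelMm = cine@pixelMm, fovRotationDeg = rotationDeg,
               nFramesCycle = cine@nFramesCycle)
}

#' Analytic phantom annotations
#'
#' Builds the [ContourSet-class] a human annotator would supply, from the
#' analytic ground truth: endo-/epicardial polygons at a set of key frames,
#' the two papillary landmarks, the static-tissue patches, no fold-over
#' regions, and the end-diastolic frame index (frame 1: acquisition is
#' triggered at the R peak).  With `rotationDeg` nonzero all geometry is
#' expressed in the rotated acquisition's image frame.
#'
#' @param truth a [GroundTruth-class]
#' @param rotationDeg FOV rotation of the acquisition being annotated (deg)
#' @param keyFrames frame indices to annotate; the default places them at
#'   end-diastole and at 10/20/30/40 % of the cycle (the deforming part)
#' @param nVertices vertices per annotated polygon (default 256, matching
#'   the contour-interpolation resampling so phantom vertices survive the
#'   resampling exactly)
#' @return a [ContourSet-class]
#' @export
phantomAnnotations <- function(truth, rotationDeg = 0, keyFrames = NULL,
                               nVertices = 256L) {
  spec <- truth@spec
  if (is.null(keyFrames))
    keyFrames <- unique(pmin(round(c(0, 0.1, 0.2, 0.3, 0.4) *
                                     spec@nFrames) + 1, spec@nFrames))
  beta <- rotationDeg * pi / 180
  Rb <- .rotMat(-beta)
  epi <- list(); endo <- list()
  for (i in seq_along(keyFrames)) {
    t <- (keyFrames[i] - 1) * spec@frameMs
    cc <- truth@contoursFn(t, n = nVertices)
    epi[[i]] <- cc$epi %*% t(Rb)
    endo[[i]] <- cc$endo %*% t(Rb)
  }
  papAng <- spec@papillaryAngleRad + c(0, -2.2)
  pap <- cbind(0.8 * spec@rEndoMm * cos(papAng),
               0.8 * spec@rEndoMm * sin(papAng)) %*% t(Rb)
  statics <- lapply(.staticPatches(spec), function(p) p %*% t(Rb))
  methods::new("ContourSet", keyFrames = as.integer(keyFrames),
               epi = epi, endo = endo, papillary = pap,
               foldover = list(), staticRegions = statics,
               tLastDiastole = 1L)
}
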
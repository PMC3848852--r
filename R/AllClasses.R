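#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- PhantomSpec

#' Synthetic acquisition specification
#'
#' Parameters of the deforming-annulus phantom.  Defaults reproduce the
#' acquisition geometry the method targets: a rat mid-ventricular short-axis
#' slice, 128 x 128 matrix over a 50 x 50 mm field of view, 70 frames at
#' 3.2 ms and an encoding velocity (venc) of 13.9 cm/s, with a contracting,
#' twisting incompressible annulus as the left-ventricular wall.
#'
#' @slot gridSize pixels per image dimension
#' @slot fovMm field of view in mm
#' @slot nFrames frames covering one cardiac cycle
#' @slot frameMs frame spacing (temporal resolution) in ms
#' @slot vencCmS encoding velocity in cm/s (velocity mapped to phase pi)
#' @slot rEndoMm,rEpiMm end-diastolic endo-/epicardial radii in mm
#' @slot contractionAmplitude peak fractional shortening of the mid-wall
#'   radius (0.19 gives a mid-wall circumferential strain of -19 %strain)
#' @slot rotationAmplitudeRad peak rigid twist in radians
#' @slot longitudinalAmplitudeCmS peak uniform through-plane velocity in cm/s
#' @slot systoleFraction fraction of the cycle occupied by the raised-cosine
#'   activation pulse
#' @slot segmentDelaysMs length-32 per-segment activation delays in ms
#' @slot hypokinesiaMask length-32 per-segment amplitude scalings in [0, 1]
#' @slot driftCmS spurious spatially-uniform in-plane velocity offset
#'   (cm/s) added over the whole FOV at render time, emulating a residual
#'   background-phase error
#' @slot ghostAmplitude relative intensity of the simulated phase-encode
#'   ghost replica
#' @slot fovRotationDeg in-plane rotation of the second acquisition (deg)
#' @slot nCoils simulated receive channels
#' @slot papillaryAngleRad angle of the anterior papillary landmark at
#'   end-diastole (the segment-counting anchor)
#' @slot seed random seed driving coil sensitivities and ghost realizations
#' @export
setClass("PhantomSpec",
  representation(
    gridSize = "integer", fovMm = "numeric", nFrames = "integer",
    frameMs = "numeric", vencCmS = "numeric",
    rEndoMm = "numeric", rEpiMm = "numeric",
    contractionAmplitude = "numeric", rotationAmplitudeRad = "numeric",
    longitudinalAmplitudeCmS = "numeric", systoleFraction = "numeric",
    segmentDelaysMs = "numeric", hypokinesiaMask = "numeric",
    driftCmS = "numeric", ghostAmplitude = "numeric",
    fovRotationDeg = "numeric", nCoils = "integer",
    papillaryAngleRad = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@rEndoMm >= object@rEpiMm)
    msg <- c(msg, "rEndoMm must be smaller than rEpiMm")
  if (object@nFrames < 8L) msg <- c(msg, "nFrames must be >= 8")
  if (length(object@segmentDelaysMs) != 32L)
    msg <- c(msg, "segmentDelaysMs must have length 32")
  if (length(object@hypokinesiaMask) != 32L)
    msg <- c(msg, "hypokinesiaMask must have length 32")
  if (any(object@hypokinesiaMask < 0 | object@hypokinesiaMask > 1))
    msg <- c(msg, "hypokinesiaMask values must lie in [0, 1]")
  if (object@contractionAmplitude < 0 || object@contractionAmplitude >= 1)
    msg <- c(msg, "contractionAmplitude must lie in [0, 1)")
  if (object@systoleFraction <= 0 || object@systoleFraction > 1)
    msg <- c(msg, "systoleFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

# --------------------------------------------------------------- GroundTruth

#' Analytic phantom ground truth
#'
#' Closed-form description of the phantom deformation: an Eulerian velocity
#' field, the Lagrangian displacement map from end-diastole, the exact
#' per-segment circumferential strain, and analytic contour polygons.
#' Produced by [makeMotionModel()].
#'
#' @slot velocityFn function(x_mm, y_mm, t_ms) -> n x 3 velocity (cm/s)
#' @slot displacementFn function(x0 (n x 2 mm), t_ms) -> n x 2 position (mm)
#' @slot strainFn function(segment (0-based), t_ms) -> circumferential
#'   Lagrangian strain (dimensionless) at the mid-wall radius
#' @slot contoursFn function(t_ms, n) -> list(epi, endo) polygon matrices
#' @slot annulusFn function(x_mm, y_mm, t_ms) -> logical, inside myocardium
#' @slot refAngle papillary reference angle (rad) at end-diastole
#' @slot spec the generating [PhantomSpec-class]
#' @export
setClass("GroundTruth",
  representation(velocityFn = "function", displacementFn = "function",
                 strainFn = "function", contoursFn = "function",
                 annulusFn = "function", refAngle = "numeric",
                 spec = "PhantomSpec"))

# -------------------------------------------------------- EncodedAcquisition

#' Velocity-encoded multi-coil acquisition
#'
#' Complex image series for the nine velocity-encoding points of a balanced
#' nine-point scheme, one series per receive coil, together with the gradient
#' first-moment matrix.  Encoding point 1 (index 0 in the schema) is the
#' velocity-compensated reference; the moment rows are normalized so that a
#' velocity equal to venc along a unit-moment row yields a phase of pi.
#'
#' @slot data complex array with dimensions
#'   (encoding point 1..9, frame, y, x, coil)
#' @slot moments 9 x 3 normalized gradient first-moment matrix
#' @slot vencCmS encoding velocity (cm/s)
#' @slot frameMs frame spacing (ms)
#' @slot pixelMm pixel size (mm)
#' @slot fovRotationDeg in-plane rotation of this acquisition (deg)
#' @slot nFramesCycle index of the last frame belonging to one cardiac cycle
#' @export
setClass("EncodedAcquisition",
  representation(data = "array", moments = "matrix", vencCmS = "numeric",
                 frameMs = "numeric", pixelMm = "numeric",
                 fovRotationDeg = "numeric", nFramesCycle = "integer"))

setValidity("EncodedAcquisition", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 5L || dim(object@data)[1] != 9L)
    msg <- c(msg, "data must be a 5-d array with 9 encoding points first")
  if (!all(dim(object@moments) == c(9L, 3L)))
    msg <- c(msg, "moments must be 9 x 3")
  else {
    d <- sweep(object@moments[-1, , drop = FALSE], 2, object@moments[1, ])
    if (qr(d)$rank < 3L)
      msg <- c(msg, "moment rows must span 3D after subtracting the reference")
  }
  if (object@nFramesCycle > dim(object@data)[2])
    msg <- c(msg, "nFramesCycle exceeds the number of frames")
  if (length(msg)) msg else TRUE
})

setMethod("nFrames", "EncodedAcquisition", function(object) dim(object@data)[2])
setMethod("frameMs", "EncodedAcquisition", function(object) object@frameMs)
setMethod("pixelMm", "EncodedAcquisition", function(object) object@pixelMm)
setMethod("venc", "EncodedAcquisition", function(object) object@vencCmS)

setMethod("show", "EncodedAcquisition", function(object) {
  d <- dim(object@data)
  cat("EncodedAcquisition:", d[1], "encoding points,", d[2], "frames,",
      d[4], "x", d[3], "matrix,", d[5], "coil(s)\n")
  cat("  venc", object@vencCmS, "cm/s | TR", object@frameMs, "ms | pixel",
      signif(object@pixelMm, 4), "mm | FOV rotation",
      object@fovRotationDeg, "deg\n")
})

# -------------------------------------------------------------- VelocityCine

#' Three-component velocity cine
#'
#' Per-frame, per-pixel velocity in cm/s (components ordered x, y,
#' z = through-plane) plus a magnitude image, with the acquisition timing and
#' grid metadata needed downstream.
#'
#' @slot velocity numeric array (frame, y, x, component), cm/s
#' @slot magnitude numeric array (frame, y, x)
#' @slot wrapped logical array (frame, y, x); TRUE where an encoded phase was
#'   close enough to +/-pi that velocity aliasing is suspected (such pixels
#'   are removed from myocardial masks downstream; no unwrapping is done)
#' @slot vencCmS encoding velocity (cm/s)
#' @slot frameMs frame spacing (ms)
#' @slot pixelMm pixel size (mm)
#' @slot nFramesCycle last frame of one cardiac cycle (the acquisition may
#'   cover more than one R-R interval)
#' @export
setClass("VelocityCine",
  representation(velocity = "array", magnitude = "array", wrapped = "array",
                 vencCmS = "numeric", frameMs = "numeric", pixelMm = "numeric",
                 nFramesCycle = "integer"))

setValidity("VelocityCine", function(object) {
  msg <- character()
  dv <- dim(object@velocity)
  if (length(dv) != 4L || dv[4] != 3L)
    msg <- c(msg, "velocity must be (frame, y, x, 3)")
  if (!all(is.finite(object@velocity)))
    msg <- c(msg, "velocity values must be finite")
  if (object@frameMs <= 0) msg <- c(msg, "frameMs must be positive")
  if (object@nFramesCycle > dv[1])
    msg <- c(msg, "nFramesCycle exceeds the number of frames")
  if (length(msg)) msg else TRUE
})

setMethod("nFrames", "VelocityCine", function(object) dim(object@velocity)[1])
setMethod("frameMs", "VelocityCine", function(object) object@frameMs)
setMethod("pixelMm", "VelocityCine", function(object) object@pixelMm)
setMethod("venc", "VelocityCine", function(object) object@vencCmS)
setMethod("velocity", "VelocityCine", function(object) object@velocity)
setMethod("magnitude", "VelocityCine", function(object) object@magnitude)

setMethod("show", "VelocityCine", function(object) {
  d <- dim(object@velocity)
  cat("VelocityCine:", d[1], "frames,", d[3], "x", d[2], "matrix\n")
  cat("  venc", object@vencCmS, "cm/s | TR", object@frameMs, "ms | pixel",
      signif(object@pixelMm, 4), "mm | cycle frames", object@nFramesCycle,
      "\n")
  cat("  in-plane speed range",
      paste(signif(range(sqrt(object@velocity[, , , 1]^2 +
                                object@velocity[, , , 2]^2)), 3),
            collapse = " .. "), "cm/s\n")
})

# ---------------------------------------------------------------- ContourSet

#' Myocardial contour annotations
#'
#' The four human inputs the post-processing needs: endo-/epicardial border
#' polygons at key frames, the papillary landmark positions, fold-over
#' exclusion polygons, and the last-diastolic frame index.  Optionally a set
#' of static-tissue polygons used by the eddy-current phase correction.
#'
#' @slot keyFrames integer frame indices of the annotated key frames
#' @slot epi,endo lists (one polygon matrix per key frame, mm coordinates)
#' @slot papillary 2 x 2 matrix of papillary landmark positions (mm); the
#'   first row anchors segment 0
#' @slot foldover list of exclusion polygons (possibly empty)
#' @slot staticRegions list of static-tissue polygons (possibly empty)
#' @slot tLastDiastole index of the end-diastolic frame
#' @export
setClass("ContourSet",
  representation(keyFrames = "integer", epi = "list", endo = "list",
                 papillary = "matrix", foldover = "list",
                 staticRegions = "list", tLastDiastole = "integer"))

setValidity("ContourSet", function(object) {
  msg <- character()
  if (length(object@epi) != length(object@keyFrames) ||
      length(object@endo) != length(object@keyFrames))
    msg <- c(msg, "one epi and one endo polygon required per key frame")
  for (i in seq_along(object@keyFrames)) {
    if (nrow(object@epi[[i]]) < 3L || nrow(object@endo[[i]]) < 3L) {
      msg <- c(msg, "polygons need at least 3 vertices")
      break
    }
    inside <- .inPoly(object@endo[[i]][, 1], object@endo[[i]][, 2],
                      object@epi[[i]])
    if (!all(inside)) {
      msg <- c(msg, "endocardial polygon must lie inside the epicardial one")
      break
    }
  }
  if (!all(dim(object@papillary) == c(2L, 2L)))
    msg <- c(msg, "papillary must be a 2 x 2 matrix")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ContourSet", function(object) {
  cat("ContourSet:", length(object@keyFrames), "key frame(s) [",
      paste(object@keyFrames, collapse = ", "), "],",
      length(object@foldover), "fold-over region(s),",
      length(object@staticRegions), "static region(s)\n")
  cat("  end-diastolic frame:", object@tLastDiastole, "\n")
})

# -------------------------------------------------------------- SegmentModel

#' Per-frame myocardial mask and 32-segment division
#'
#' Pixel mask between the interpolated contours, the angular segment index of
#' every masked pixel (anchored at the papillary reference and following the
#' LV through the cycle), the per-frame LV centre, and the per-frame contour
#' polygons.
#'
#' @slot mask logical array (frame, y, x)
#' @slot segmentMap integer array (frame, y, x); 0-based segment index, NA
#'   outside the mask
#' @slot center per-frame LV centre (frames x 2, mm)
#' @slot refAngle per-frame papillary reference angle (rad)
#' @slot nSegments number of angular segments (default 32)
#' @slot direction segment counting direction ("ccw" or "cw")
#' @slot pixelMm pixel size (mm)
#' @slot epiPolys,endoPolys per-frame interpolated contour polygons
#' @slot tED end-diastolic frame index carried from the annotations
#' @export
setClass("SegmentModel",
  representation(mask = "array", segmentMap = "array", center = "matrix",
                 refAngle = "numeric", nSegments = "integer",
                 direction = "character", pixelMm = "numeric",
                 epiPolys = "list", endoPolys = "list", tED = "integer"))

setValidity("SegmentModel", function(object) {
  msg <- character()
  if (any(apply(object@mask, 1, sum) == 0))
    msg <- c(msg, "empty myocardial mask at some frame")
  bad <- object@mask & is.na(object@segmentMap)
  if (any(bad))
    msg <- c(msg, "every masked pixel must carry a segment index")
  if (length(msg)) msg else TRUE
})

setMethod("nFrames", "SegmentModel", function(object) dim(object@mask)[1])
setMethod("nSegments", "SegmentModel", function(object) object@nSegments)
setMethod("myoMask", "SegmentModel", function(object) object@mask)
setMethod("segmentMap", "SegmentModel", function(object) object@segmentMap)
setMethod("lvCenter", "SegmentModel", function(object) object@center)
setMethod("pixelMm", "SegmentModel", function(object) object@pixelMm)

setMethod("show", "SegmentModel", function(object) {
  cat("SegmentModel:", dim(object@mask)[1], "frames,", object@nSegments,
      "segments (", object@direction, "),",
      round(mean(apply(object@mask, 1, sum))), "masked pixels/frame\n")
})

# ----------------------------------------------------------- CardiopolarCine

#' Cardiopolar velocity decomposition
#'
#' Per-pixel radial / tangential / longitudinal velocities relative to the
#' per-frame LV centre.  Radial velocity is positive towards the centre
#' (contraction positive).
#'
#' @slot radial,tangential,longitudinal numeric arrays (frame, y, x), cm/s
#' @slot frameMs frame spacing (ms)
#' @slot pixelMm pixel size (mm)
#' @export
setClass("CardiopolarCine",
  representation(radial = "array", tangential = "array",
                 longitudinal = "array", frameMs = "numeric",
                 pixelMm = "numeric"))

setMethod("nFrames", "CardiopolarCine", function(object) dim(object@radial)[1])
setMethod("frameMs", "CardiopolarCine", function(object) object@frameMs)

# --------------------------------------------------------------- WaveformSet

#' Global and regional velocity waveforms
#'
#' @slot global per-frame global value (mean over all mask pixels, not the
#'   mean of segment means)
#' @slot regional nSegments x nFrames matrix of segment means
#' @slot component "radial", "tangential" or "longitudinal"
#' @slot timeMs frame times (ms)
#' @slot imputed logical matrix flagging regional values carried over from
#'   the nearest frame with data (empty segment at that frame)
#' @export
setClass("WaveformSet",
  representation(global = "numeric", regional = "matrix",
                 component = "character", timeMs = "numeric",
                 imputed = "matrix"))

setValidity("WaveformSet", function(object) {
  msg <- character()
  if (ncol(object@regional) != length(object@global))
    msg <- c(msg, "regional columns must match global length")
  if (length(object@timeMs) != length(object@global))
    msg <- c(msg, "timeMs must match global length")
  if (length(msg)) msg else TRUE
})

setMethod("globalCurve", "WaveformSet", function(object) object@global)
setMethod("regionalCurves", "WaveformSet", function(object) object@regional)
setMethod("timeMs", "WaveformSet", function(object) object@timeMs)
setMethod("nFrames", "WaveformSet", function(object) length(object@global))

setMethod("show", "WaveformSet", function(object) {
  cat("WaveformSet (", object@component, "): ", nrow(object@regional),
      " segments x ", length(object@global), " frames; global range ",
      paste(signif(range(object@global), 3), collapse = " .. "), " cm/s\n",
      sep = "")
})

# ------------------------------------------------------------- KeyTimepoints

#' Key cardiac-cycle timepoints
#'
#' @slot tPeakSystole frame of peak global radial velocity
#' @slot tEndSystole frame of minimum LV lumen (endocardial polygon) area
#' @slot tED end-diastolic frame (from the annotations)
#' @export
setClass("KeyTimepoints",
  representation(tPeakSystole = "integer", tEndSystole = "integer",
                 tED = "integer"))

setMethod("show", "KeyTimepoints", function(object) {
  cat("KeyTimepoints: ED frame", object@tED, "| peak systole frame",
      object@tPeakSystole, "| end systole frame", object@tEndSystole, "\n")
})

# ------------------------------------------------------------- TrajectorySet

#' Per-pixel myocardial trajectories
#'
#' Closed motion paths obtained by forward-backward Fourier tracking of the
#' velocity cine, seeded at every mask pixel of the origin frame.
#'
#' @slot paths numeric array (seed, frame, 2) of positions in mm, indexed by
#'   absolute cycle frame
#' @slot seedsMm seed positions (n x 2, mm) at the origin frame
#' @slot seedSegment 0-based segment index of each seed at the origin frame
#' @slot valid per-seed validity flag
#' @slot originFrame temporal origin of the integration (ED or ES frame)
#' @slot frameMs frame spacing (ms)
#' @slot pixelMm pixel size (mm)
#' @export
setClass("TrajectorySet",
  representation(paths = "array", seedsMm = "matrix",
                 seedSegment = "integer", valid = "logical",
                 originFrame = "integer", frameMs = "numeric",
                 pixelMm = "numeric"))

setMethod("trajPaths", "TrajectorySet", function(object) object@paths)
setMethod("validPaths", "TrajectorySet", function(object) object@valid)
setMethod("originFrame", "TrajectorySet", function(object) object@originFrame)
setMethod("nFrames", "TrajectorySet", function(object) dim(object@paths)[2])

setMethod("show", "TrajectorySet", function(object) {
  cat("TrajectorySet:", nrow(object@seedsMm), "seeds (",
      sum(object@valid), "valid ) over", dim(object@paths)[2],
      "frames; origin frame", object@originFrame, "\n")
})

# ------------------------------------------------------------ StrainCurveSet

#' Segmental circumferential strain curves
#'
#' Lagrangian circumferential strain per segment computed from the chord
#' between the two neighbouring segments' mean trajectory positions,
#' referenced to the end-diastolic frame.  Values are dimensionless
#' (multiply by 100 for %strain).
#'
#' @slot sc nSegments x nFrames strain matrix (dimensionless; NA = flagged
#'   missing)
#' @slot globalSc per-frame unweighted mean over available segments
#' @slot xs numeric array (segment, frame, 2): mean in-plane position of the
#'   valid trajectories seeded in each segment
#' @slot origin "ED", "ES" or "averaged"
#' @slot tED end-diastolic frame index (the strain reference frame)
#' @slot timeMs frame times (ms)
#' @export
setClass("StrainCurveSet",
  representation(sc = "matrix", globalSc = "numeric", xs = "array",
                 origin = "character", tED = "integer", timeMs = "numeric"))

setValidity("StrainCurveSet", function(object) {
  msg <- character()
  ok <- !is.na(object@sc[, object@tED])
  if (any(abs(object@sc[ok, object@tED]) > 1e-9))
    msg <- c(msg, "strain at the end-diastolic frame must be zero")
  if (length(msg)) msg else TRUE
})

setMethod("sc", "StrainCurveSet", function(object) object@sc)
setMethod("globalSc", "StrainCurveSet", function(object) object@globalSc)
setMethod("timeMs", "StrainCurveSet", function(object) object@timeMs)
setMethod("nFrames", "StrainCurveSet", function(object) ncol(object@sc))
setMethod("nSegments", "StrainCurveSet", function(object) nrow(object@sc))

setMethod("show", "StrainCurveSet", function(object) {
  cat("StrainCurveSet (origin ", object@origin, "): ", nrow(object@sc),
      " segments x ", ncol(object@sc), " frames; peak global Sc ",
      signif(100 * min(object@globalSc, na.rm = TRUE), 4), " %strain\n",
      sep = "")
})
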
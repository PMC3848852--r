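#' @include AllClasses.R
NULL

#' Forward-backward Fourier trajectory tracking
#'
#' Computes a closed motion path for every myocardial pixel of the origin
#' frame.  From each seed the velocity field is integrated forward over one
#' full cycle and backward likewise (explicit Euler, step = frame spacing,
#' velocity looked up by nearest neighbour in space at the current position
#' and frame-wise in time, frames wrapping periodically).  The two passes
#' are blended linearly in elapsed time,
#' `x(t') = (1 - t'/T) x_fwd(t') + (t'/T) x_bwd(t')`,
#' which enforces exact closure of every path: the blended position one full
#' cycle after the origin coincides with the seed to floating-point
#' precision.  Velocity outside the myocardial mask (but inside the FOV) is
#' used as-is during integration; paths are judged against the mask only by
#' [filterTrajectories()].  A path whose position leaves the FOV is marked
#' invalid.
#'
#' @param cine a bulk-corrected [VelocityCine-class] covering one cycle
#' @param model a [SegmentModel-class]
#' @param origin integer origin frame (typically the ED or ES frame)
#' @param scheme `"fourier"` (the forward-backward blend) or `"forward"`
#'   (pure forward integration, for diagnostics; paths then need not close)
#' @return a [TrajectorySet-class]
#' @export
fourierTrack <- function(cine, model, origin,
                         scheme = c("fourier", "forward")) {
  scheme <- match.arg(scheme)
  nF <- cine@nFramesCycle
  d <- dim(cine@velocity)
  ny <- d[2]; nx <- d[3]
  px <- cine@pixelMm
  origin <- as.integer(origin)
  stopifnot(origin >= 1, origin <= nF)
  dtMs <- cine@frameMs
  m0 <- model@mask[origin, , ]
  idx <- which(m0)                     # column-major over (y, x)
  iy <- ((idx - 1) %% ny) + 1
  ix <- ((idx - 1) %/% ny) + 1
  seeds <- cbind((ix - 1 - (nx - 1) / 2) * px,
                 (iy - 1 - (ny - 1) / 2) * px)
  nSeed <- nrow(seeds)
  segAtSeed <- model@segmentMap[origin, , ][idx]
  # velocity lookup (cm/s) by nearest pixel at a given frame
  lookup <- function(pos, f, invalid) {
    jx <- round(pos[, 1] / px + (nx - 1) / 2) + 1
    jy <- round(pos[, 2] / px + (ny - 1) / 2) + 1
    out <- jx < 1 | jx > nx | jy < 1 | jy > ny | invalid
    jx[out] <- 1; jy[out] <- 1
    lin <- (jx - 1) * ny + jy
    vx <- cine@velocity[f, , , 1][lin]
    vy <- cine@velocity[f, , , 2][lin]
    vx[out] <- 0; vy[out] <- 0
    list(v = cbind(vx, vy), out = out)
  }
  frameOf <- function(k) ((origin - 1 + k) %% nF) + 1
  step <- dtMs * .CMS_TO_MM_PER_MS
  valid <- rep(TRUE, nSeed)
  # forward pass: fwd[[k + 1]] is the position at elapsed k frames
  fwd <- vector("list", nF + 1)
  fwd[[1]] <- seeds
  pos <- seeds
  for (k in seq_len(nF)) {
    lk <- lookup(pos, frameOf(k - 1), !valid)
    valid <- valid & !lk$out
    pos <- pos + lk$v * step
    fwd[[k + 1]] <- pos
  }
  paths <- array(NA_real_, c(nSeed, nF, 2))
  if (scheme == "forward") {
    for (k in 0:(nF - 1)) paths[, frameOf(k), ] <- fwd[[k + 1]]
  } else {
    # backward pass: bwd[[k + 1]] estimates the position at elapsed k via
    # integration backward from the seed (nF - k steps)
    bwd <- vector("list", nF + 1)
    bwd[[nF + 1]] <- seeds
    pos <- seeds
    for (k in (nF - 1):0) {
      lk <- lookup(pos, frameOf(k), !valid)
      valid <- valid & !lk$out
      pos <- pos - lk$v * step
      bwd[[k + 1]] <- pos
    }
    for (k in 0:(nF - 1)) {
      w <- k / nF
      paths[, frameOf(k), ] <- (1 - w) * fwd[[k + 1]] + w * bwd[[k + 1]]
    }
  }
  methods::new("TrajectorySet", paths = paths, seedsMm = seeds,
               seedSegment = as.integer(segAtSeed), valid = valid,
               originFrame = origin, frameMs = dtMs, pixelMm = px)
}

#' Discard trajectories leaving the myocardial mask
#'
#' Invalidates every path whose position at any frame falls outside that
#' frame's myocardial mask.  Membership is judged against the continuous
#' form of the mask -- inside the epicardial and outside the endocardial
#' contour polygon of that frame -- so that paths hugging the wall are not
#' spuriously discarded by half-pixel rasterization of the boundary
#' (`useContours = FALSE` switches to strict nearest-pixel membership in the
#' rasterized mask).  No other filtering or smoothing is applied to the
#' surviving paths.
#'
#' @param traj a [TrajectorySet-class]
#' @param model a [SegmentModel-class]
#' @param useContours judge membership by the contour band (default) rather
#'   than the rasterized pixel mask
#' @return the filtered [TrajectorySet-class]
#' @export
filterTrajectories <- function(traj, model, useContours = TRUE) {
  d <- dim(model@mask)
  nF <- d[1]; ny <- d[2]; nx <- d[3]
  px <- traj@pixelMm
  ok <- traj@valid
  for (f in seq_len(min(nF, dim(traj@paths)[2]))) {
    if (useContours) {
      inMask <- .inPoly(traj@paths[, f, 1], traj@paths[, f, 2],
                        model@epiPolys[[f]]) &
        !.inPoly(traj@paths[, f, 1], traj@paths[, f, 2],
                 model@endoPolys[[f]])
    } else {
      jx <- round(traj@paths[, f, 1] / px + (nx - 1) / 2) + 1
      jy <- round(traj@paths[, f, 2] / px + (ny - 1) / 2) + 1
      out <- jx < 1 | jx > nx | jy < 1 | jy > ny
      jx[out] <- 1; jy[out] <- 1
      lin <- (jx - 1) * ny + jy
      inMask <- model@mask[f, , ][lin] & !out
    }
    ok <- ok & inMask
  }
  if (!any(ok)) stop("tracking failed: all trajectories left the mask")
  traj@valid <- ok
  traj
}
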
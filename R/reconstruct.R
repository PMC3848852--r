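#' @include AllClasses.R
NULL

#' Multi-coil phase-difference combination
#'
#' Combines the receive channels of a velocity-encoded acquisition by
#' complex-conjugate multiplication of each encoded series with the
#' velocity-compensated reference series, individually per coil, then summing
#' over coils before taking the argument:
#' `phase_e = arg( sum_coils S_e * conj(S_0) )`.
#' Coil phases cancel in the conjugate product, and each coil contributes
#' with weight `|S_e||S_0|`.  The magnitude image is
#' `sqrt( sum_coils |S_0|^2 )`.
#'
#' @param acq an [EncodedAcquisition-class]
#' @return a list with elements `phase` (array: encoded point 1..8, frame, y,
#'   x, in radians), `magnitude` (frame, y, x), `lowSignal` (logical, pixels
#'   with vanishing combined signal whose phase was set to 0) and the
#'   acquisition metadata (`moments`, `vencCmS`, `frameMs`, `pixelMm`,
#'   `nFramesCycle`)
#' @export
combineCoils <- function(acq) {
  d <- dim(acq@data)
  nF <- d[2]; ny <- d[3]; nx <- d[4]; nc <- d[5]
  phase <- array(0, c(8, nF, ny, nx))
  ref <- acq@data[1, , , , , drop = FALSE]
  dim(ref) <- c(nF, ny, nx, nc)
  mag2 <- apply(abs(ref)^2, c(1, 2, 3), sum)
  lowSignal <- array(FALSE, c(nF, ny, nx))
  for (e in 2:9) {
    enc <- acq@data[e, , , , , drop = FALSE]
    dim(enc) <- c(nF, ny, nx, nc)
    pick <- function(a, k) {
      out <- a[, , , k, drop = FALSE]
      dim(out) <- c(nF, ny, nx)
      out
    }
    s <- pick(enc, 1) * Conj(pick(ref, 1))
    if (nc > 1) for (k in 2:nc) s <- s + pick(enc, k) * Conj(pick(ref, k))
    low <- abs(s) < 1e-300
    lowSignal <- lowSignal | low
    ph <- Arg(s)
    ph[low] <- 0
    phase[e - 1, , , ] <- ph
  }
  list(phase = phase, magnitude = sqrt(mag2), lowSignal = lowSignal,
       moments = acq@moments, vencCmS = acq@vencCmS, frameMs = acq@frameMs,
       pixelMm = acq@pixelMm, nFramesCycle = acq@nFramesCycle)
}

#' Eddy-current background phase correction
#'
#' Polynomial surrogate for spatially specific eddy-current correction: for
#' each encoded point a 2D polynomial of the given order is least-squares
#' fitted to the temporal-mean phase over user-declared static tissue
#' (excluding fold-over regions), and the fitted surface is subtracted from
#' every frame.  An order-`k` fit exactly removes any additive polynomial
#' phase field of order `<= k`.
#'
#' @param maps the list returned by [combineCoils()]
#' @param staticMask logical (y, x) matrix of static-tissue pixels
#' @param exclusionMask optional logical (y, x) matrix of pixels to exclude
#'   (fold-over regions)
#' @param order polynomial order of the fitted surface (default 1, a plane)
#' @return `maps` with corrected `phase` and an added `eddyFit` element (one
#'   coefficient vector per encoded point)
#' @export
correctEddyPhase <- function(maps, staticMask, exclusionMask = NULL,
                             order = 1L) {
  d <- dim(maps$phase)
  nF <- d[2]; ny <- d[3]; nx <- d[4]
  use <- staticMask
  if (!is.null(exclusionMask)) use <- use & !exclusionMask
  idx <- which(use)
  nCoef <- (order + 1) * (order + 2) / 2
  if (length(idx) < nCoef)
    stop("insufficient static region: ", length(idx), " pixels for ",
         nCoef, " polynomial coefficients")
  # normalized pixel-centre coordinates over the full grid
  xn <- rep(.pixelCoords(nx, 2 / nx), each = ny)
  yn <- rep(.pixelCoords(ny, 2 / ny), times = nx)
  basis <- .polyBasis(xn, yn, order)
  X <- basis[idx, , drop = FALSE]
  XtXinv <- solve(crossprod(X))
  fits <- vector("list", 8)
  for (e in seq_len(8)) {
    ph <- maps$phase[e, , , ]
    dim(ph) <- c(nF, ny * nx)
    meanPh <- colMeans(ph)
    beta <- XtXinv %*% crossprod(X, meanPh[idx])
    surf <- as.numeric(basis %*% beta)
    maps$phase[e, , , ] <- ph - rep(surf, each = nF)
    fits[[e]] <- as.numeric(beta)
  }
  maps$eddyFit <- fits
  maps
}

# polynomial design matrix with terms x^i y^j, i + j <= order
.polyBasis <- function(x, y, order) {
  cols <- list()
  for (tot in 0:order)
    for (i in tot:0)
      cols[[length(cols) + 1]] <- x^i * y^(tot - i)
  do.call(cbind, cols)
}

#' Decode velocities from phase-difference maps
#'
#' Per pixel and frame, solves the linear system
#' `(pi / venc) * (M_e - M_0) v = phase_e` over the eight encoded points in
#' the least-squares sense (the per-pixel magnitude weighting discussed for
#' this decode is a scalar common to all eight equations of a pixel and
#' cancels from the normal equations).  Pixels where any encoded phase
#' magnitude reaches `pi * (1 - wrapTol)` are flagged as potentially wrapped;
#' no unwrapping is attempted.
#'
#' @param maps the (optionally eddy-corrected) list from [combineCoils()]
#' @param moments optional 9 x 3 first-moment matrix override
#' @param vencCmS optional venc override (cm/s)
#' @param wrapTol relative distance from pi at which a phase is flagged
#' @return a [VelocityCine-class]
#' @export
decodeVelocities <- function(maps, moments = maps$moments,
                             vencCmS = maps$vencCmS, wrapTol = 0.01) {
  dmat <- sweep(moments[-1, , drop = FALSE], 2, moments[1, ])
  if (qr(dmat)$rank < 3L)
    stop("rank-deficient encoding moments: velocity is not recoverable")
  A <- (pi / vencCmS) * dmat
  pinv <- solve(crossprod(A), t(A))        # 3 x 8
  d <- dim(maps$phase)
  nF <- d[2]; ny <- d[3]; nx <- d[4]
  ph <- maps$phase
  dim(ph) <- c(8, nF * ny * nx)
  v <- pinv %*% ph                         # 3 x (F*ny*nx)
  wrapped <- colSums(abs(ph) >= pi * (1 - wrapTol)) > 0
  vel <- array(0, c(nF, ny, nx, 3))
  vel[, , , 1] <- v[1, ]
  vel[, , , 2] <- v[2, ]
  vel[, , , 3] <- v[3, ]
  methods::new("VelocityCine", velocity = vel, magnitude = maps$magnitude,
               wrapped = array(wrapped | c(maps$lowSignal), c(nF, ny, nx)),
               vencCmS = vencCmS, frameMs = maps$frameMs,
               pixelMm = maps$pixelMm,
               nFramesCycle = as.integer(maps$nFramesCycle))
}

#' Reconstruct a velocity cine from an encoded acquisition
#'
#' Convenience chain: [combineCoils()], optional [correctEddyPhase()] (when a
#' static mask is supplied), then [decodeVelocities()].
#'
#' @param acq an [EncodedAcquisition-class]
#' @param staticMask optional logical (y, x) static-tissue mask for the
#'   eddy-current correction
#' @param exclusionMask optional logical (y, x) fold-over exclusion mask
#' @param eccOrder polynomial order of the correction (default 1)
#' @param ... passed on to [decodeVelocities()]
#' @return a [VelocityCine-class]
#' @export
reconstructVelocities <- function(acq, staticMask = NULL,
                                  exclusionMask = NULL, eccOrder = 1L, ...) {
  maps <- combineCoils(acq)
  if (!is.null(staticMask))
    maps <- correctEddyPhase(maps, staticMask, exclusionMask, eccOrder)
  decodeVelocities(maps, ...)
}
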
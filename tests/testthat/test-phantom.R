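test_that("zero-motion phantom has identically zero velocity and strain", {
  spec <- smallSpec(contractionAmplitude = 0, rotationAmplitudeRad = 0,
                    longitudinalAmplitudeCmS = 0)
  truth <- makeMotionModel(spec)
  set.seed(11)
  th <- runif(50, 0, 2 * pi)
  r <- runif(50, spec@rEndoMm + 0.01, spec@rEpiMm - 0.01)
  for (t in c(0, 7.3, 20, 40)) {
    expect_equal(max(abs(truth@velocityFn(r * cos(th), r * sin(th), t))), 0)
    expect_equal(max(abs(truth@strainFn(0:31, t))), 0)
  }
  cine <- renderVelocityCine(truth)
  expect_equal(max(abs(cine@velocity)), 0)
})

test_that("pure rigid rotation is tangential with speed |dtheta/dt| * r", {
  spec <- smallSpec(contractionAmplitude = 0, rotationAmplitudeRad = 0.2,
                    longitudinalAmplitudeCmS = 0)
  truth <- makeMotionModel(spec)
  t <- 10
  r <- c(3.5, 4, 4.5)
  th <- c(0.3, 2, 4)
  v <- truth@velocityFn(r * cos(th), r * sin(th), t)
  # radial component vanishes
  vr <- v[, 1] * cos(th) + v[, 2] * sin(th)
  expect_lt(max(abs(vr)), 1e-12)
  # independent oracle for the angular rate: central difference of the
  # displacement map
  h <- 1e-4
  x0 <- cbind(r * cos(th), r * sin(th))
  dpos <- (truth@displacementFn(x0, t + h) -
             truth@displacementFn(x0, t - h)) / (2 * h)  # mm/ms
  omega <- sqrt(rowSums(dpos^2)) / r
  speed <- sqrt(v[, 1]^2 + v[, 2]^2)          # cm/s
  expect_equal(speed, omega * r * 100, tolerance = 1e-6)
})

test_that("mid-wall circumferential stretch lambda gives strain lambda - 1", {
  spec <- smallSpec(contractionAmplitude = 0.10)
  truth <- makeMotionModel(spec)
  tPeak <- 0.2 * spec@nFrames * spec@frameMs  # activation pulse maximum
  expect_equal(truth@strainFn(0:31, tPeak), rep(-0.10, 32),
               tolerance = 1e-12)
  # and the radial mapping realizes exactly that stretch at the mid-wall
  rMid <- (spec@rEndoMm + spec@rEpiMm) / 2
  p <- truth@displacementFn(cbind(rMid, 0), tPeak)
  expect_equal(sqrt(sum(p^2)) / rMid, 0.9, tolerance = 1e-12)
})

test_that("annulus area is conserved to < 0.01 % at every frame", {
  truth <- defaultTruth()
  spec <- truth@spec
  a0 <- pi * (spec@rEpiMm^2 - spec@rEndoMm^2)
  for (f in seq(1, spec@nFrames, by = 7)) {
    cc <- truth@contoursFn((f - 1) * spec@frameMs, n = 1024L)
    a <- tpmcmr:::.polyArea(cc$epi) - tpmcmr:::.polyArea(cc$endo)
    expect_lt(abs(a - a0) / a0, 1e-4)
  }
})

test_that("motion paths close over one cycle and strain is zero at ED", {
  spec <- smallSpec(segmentDelaysMs = rep(c(0, 4), 16),
                    hypokinesiaMask = c(rep(0.5, 8), rep(1, 24)))
  truth <- makeMotionModel(spec)
  Tms <- spec@nFrames * spec@frameMs
  set.seed(4)
  th <- runif(40, 0, 2 * pi)
  r <- runif(40, spec@rEndoMm, spec@rEpiMm)
  x0 <- cbind(r * cos(th), r * sin(th))
  expect_equal(truth@displacementFn(x0, Tms), x0, tolerance = 1e-12)
  expect_equal(max(abs(truth@strainFn(0:31, 0))), 0)
})

test_that("delay-free strain is identical across segments; delays shift the
           analytic waveforms by exactly the imposed lag", {
  truth0 <- defaultTruth()
  tgrid <- (0:69) * 3.2   # exactly one cycle at the default frame spacing
  scm <- sapply(tgrid, function(t) truth0@strainFn(0:31, t))
  expect_equal(apply(scm, 2, function(v) max(v) - min(v)), rep(0, ncol(scm)))

  del <- rep(0, 32); del[c(3, 9, 20)] <- c(6.4, 12.8, -6.4)  # exact frames
  spec <- phantomSpec(segmentDelaysMs = del, rotationAmplitudeRad = 0)
  truth <- makeMotionModel(spec)
  rMid <- 4
  waveAt <- function(s) {
    th <- tpmcmr:::.segmentCenterAngle(s, spec@papillaryAngleRad)
    sapply(tgrid, function(t) {
      v <- truth@velocityFn(rMid * cos(th), rMid * sin(th), t)
      -(v[1] * cos(th) + v[2] * sin(th))
    })
  }
  ref <- waveAt(0)
  for (s in c(2, 8, 19)) {  # 0-based segments with imposed delays
    lag <- circularDelayFrames(waveAt(s), ref)
    expect_equal(lag * spec@frameMs, del[s + 1])
  }
})

test_that("rendered cine equals the velocity field at pixel centres", {
  spec <- smallSpec()
  truth <- makeMotionModel(spec)
  cine <- renderVelocityCine(truth)
  n <- spec@gridSize
  px <- spec@fovMm / n
  set.seed(9)
  for (i in 1:40) {
    f <- sample(spec@nFrames, 1)
    iy <- sample(n, 1); ix <- sample(n, 1)
    x <- (ix - 1 - (n - 1) / 2) * px
    y <- (iy - 1 - (n - 1) / 2) * px
    expect_equal(as.numeric(cine@velocity[f, iy, ix, ]),
                 as.numeric(truth@velocityFn(x, y, (f - 1) * spec@frameMs)),
                 tolerance = 1e-14)
  }
})

test_that("uniform drift offsets every pixel's in-plane velocity exactly", {
  truthD <- makeMotionModel(smallSpec(driftCmS = c(0.7, -0.3)))
  truth0 <- makeMotionModel(smallSpec())
  cD <- renderVelocityCine(truthD)
  c0 <- renderVelocityCine(truth0)
  expect_equal(cD@velocity[, , , 1], c0@velocity[, , , 1] + 0.7)
  expect_equal(cD@velocity[, , , 2], c0@velocity[, , , 2] - 0.3)
  expect_equal(cD@velocity[, , , 3], c0@velocity[, , , 3])
})

test_that("activation exceeding the endocardial radius is an annulus collapse", {
  expect_error(makeMotionModel(smallSpec(contractionAmplitude = 0.9)),
               "annulus collapse")
})

test_that("encoded phases equal the reference for zero velocity and reach pi
           at venc", {
  spec <- smallSpec(contractionAmplitude = 0, rotationAmplitudeRad = 0,
                    longitudinalAmplitudeCmS = 0, nCoils = 1L)
  truth <- makeMotionModel(spec)
  cine <- renderVelocityCine(truth)
  acq <- encodeAcquisition(cine, spec)
  for (e in 2:9)
    expect_lt(max(abs(Arg(acq@data[e, , , , 1] *
                            Conj(acq@data[1, , , , 1])))), 1e-12)

  # a pixel moving at venc along a unit-moment encoding row acquires
  # exactly a pi phase difference
  mom <- ninePointMoments()
  mom[2, ] <- c(1, 0, 0)
  cine2 <- cine
  cine2@velocity[1, 5, 5, 1] <- spec@vencCmS
  expect_warning(acq2 <- encodeAcquisition(cine2, spec, moments = mom),
                 "wrap")
  ph <- Arg(acq2@data[2, 1, 5, 5, 1] * Conj(acq2@data[1, 1, 5, 5, 1]))
  expect_equal(abs(ph), pi, tolerance = 1e-12)
})
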
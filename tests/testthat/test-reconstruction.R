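# helpers to build small synthetic encoded acquisitions directly
mkAcq <- function(data, moments = ninePointMoments(), venc = 13.9) {
  methods::new("EncodedAcquisition", data = data, moments = moments,
               vencCmS = venc, frameMs = 3.2, pixelMm = 1,
               fovRotationDeg = 0, nFramesCycle = dim(data)[2])
}

test_that("coil combination recovers the encoded phase and cancels coil
           phases", {
  nF <- 2L; n <- 6L
  phi <- array(runif(nF * n * n, -2, 2), c(nF, n, n))
  # one coil: S_e = S_0 exp(i phi)
  data <- array(complex(real = 0), c(9, nF, n, n, 1))
  s0 <- array(complex(modulus = 1.3, argument = 0.4), c(nF, n, n))
  data[1, , , , 1] <- s0
  for (e in 2:9) data[e, , , , 1] <- s0 * exp(1i * phi)
  maps <- combineCoils(mkAcq(data))
  for (e in 1:8) expect_equal(maps$phase[e, , , ], phi, tolerance = 1e-12)

  # two coils with equal magnitude, same encoded phase, different coil
  # phases: the conjugate product removes the coil phase
  data2 <- array(complex(real = 0), c(9, nF, n, n, 2))
  for (k in 1:2) {
    s0k <- array(complex(modulus = 1, argument = k * 1.1), c(nF, n, n))
    data2[1, , , , k] <- s0k
    for (e in 2:9) data2[e, , , , k] <- s0k * exp(1i * phi)
  }
  maps2 <- combineCoils(mkAcq(data2))
  for (e in 1:8) expect_equal(maps2$phase[e, , , ], phi, tolerance = 1e-12)
})

test_that("multi-coil combination matches a brute-force per-pixel weighted
           phase-difference oracle", {
  set.seed(21)
  nF <- 2L; n <- 5L; nc <- 4L
  data <- array(complex(real = rnorm(9 * nF * n * n * nc),
                        imaginary = rnorm(9 * nF * n * n * nc)),
                c(9, nF, n, n, nc))
  maps <- combineCoils(mkAcq(data))
  for (e in 2:9) for (f in 1:nF) for (iy in 1:n) for (ix in 1:n) {
    w <- abs(data[e, f, iy, ix, ]) * abs(data[1, f, iy, ix, ])
    dphi <- Arg(data[e, f, iy, ix, ]) - Arg(data[1, f, iy, ix, ])
    oracle <- Arg(sum(w * exp(1i * dphi)))
    expect_equal(maps$phase[e - 1, f, iy, ix], oracle, tolerance = 1e-10)
  }
  # magnitude image oracle
  expect_equal(maps$magnitude,
               sqrt(apply(abs(data[1, , , , , drop = FALSE])^2, 2:4, sum)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("coil combination is invariant to per-coil global phase offsets", {
  set.seed(22)
  nF <- 1L; n <- 6L; nc <- 3L
  data <- array(complex(real = rnorm(9 * nF * n * n * nc),
                        imaginary = rnorm(9 * nF * n * n * nc)),
                c(9, nF, n, n, nc))
  shifted <- data
  for (k in 1:nc) shifted[, , , , k] <- data[, , , , k] * exp(1i * k * 0.77)
  expect_equal(combineCoils(mkAcq(data))$phase,
               combineCoils(mkAcq(shifted))$phase, tolerance = 1e-12)
})

test_that("order-1 eddy correction exactly removes planar phase ramps, also
           with a fold-over patch excluded from the fit", {
  spec <- smallSpec(nCoils = 1L)
  truth <- makeMotionModel(spec)
  cine <- renderVelocityCine(truth)
  acq <- encodeAcquisition(cine, spec)
  maps0 <- combineCoils(acq)
  n <- spec@gridSize
  co <- tpmcmr:::.pixelCoords(n, 2 / n)
  ramp <- outer(rep(1, n), co) * 0.4 - outer(co, rep(1, n)) * 0.25 + 0.1
  maps <- maps0
  for (e in 1:8)
    maps$phase[e, , , ] <- maps$phase[e, , , ] +
      rep(ramp, each = dim(maps$phase)[2])
  # static tissue = pixels that are never bright moving myocardium
  staticMask <- apply(cine@magnitude, c(2, 3), max) < 0.9
  corrected <- correctEddyPhase(maps, staticMask)
  expect_equal(corrected$phase, maps0$phase, tolerance = 1e-10)
  # zero phase in, zero correction out
  expect_equal(correctEddyPhase(maps0, staticMask)$phase, maps0$phase,
               tolerance = 1e-12)

  # localized "fold-over" contamination inside the static region: once
  # excluded from the fit, the fitted plane is unaffected and the clean
  # pixels are restored exactly (least-squares oracle: the exact ramp)
  patch <- matrix(FALSE, n, n); patch[1:10, 1:10] <- TRUE
  nF <- dim(maps$phase)[2]
  contam <- array(rep(2.5 * patch, each = nF), c(nF, n, n))
  mapsP <- maps
  mapsP$phase[1, , , ] <- mapsP$phase[1, , , ] + contam
  correctedP <- correctEddyPhase(mapsP, staticMask, exclusionMask = patch)
  keep <- array(rep(!patch, each = nF), c(nF, n, n))
  expect_lt(max(abs((correctedP$phase[1, , , ] -
                       maps0$phase[1, , , ])[keep])), 1e-8)
})

test_that("zero phase decodes to zero velocity; a forward-modelled phase
           round-trips exactly; pi phase on a unit x row gives venc", {
  mom <- ninePointMoments()
  nF <- 1L; n <- 4L
  zero <- list(phase = array(0, c(8, nF, n, n)),
               magnitude = array(1, c(nF, n, n)),
               lowSignal = array(FALSE, c(nF, n, n)), moments = mom,
               vencCmS = 13.9, frameMs = 3.2, pixelMm = 1, nFramesCycle = nF)
  expect_equal(max(abs(decodeVelocities(zero)@velocity)), 0)

  set.seed(31)
  v <- matrix(runif(n * n * 3, -8, 8), ncol = 3)
  maps <- zero
  for (e in 1:8)
    maps$phase[e, 1, , ] <- matrix((pi / 13.9) * (v %*% mom[e + 1, ]), n, n)
  dec <- decodeVelocities(maps)
  for (k in 1:3)
    expect_equal(as.numeric(dec@velocity[1, , , k]), v[, k],
                 tolerance = 1e-10)

  momX <- mom; momX[2, ] <- c(1, 0, 0)
  mapsX <- zero; mapsX$moments <- momX
  vX <- cbind(rep(13.9, n * n), 0, 0)
  for (e in 1:8)
    mapsX$phase[e, 1, , ] <- matrix((pi / 13.9) * (vX %*% momX[e + 1, ]),
                                    n, n)
  decX <- decodeVelocities(mapsX)
  expect_equal(as.numeric(decX@velocity[1, , , 1]), rep(13.9, n * n),
               tolerance = 1e-10)
  expect_true(all(decX@wrapped))   # |phase| = pi flagged as wrapped

  badMom <- mom; badMom[2:9, 3] <- 0
  expect_error(decodeVelocities(maps, moments = badMom), "rank")
})

test_that("encode followed by decode is the identity for |v| < venc", {
  spec <- smallSpec(nCoils = 1L)
  truth <- makeMotionModel(spec)
  cine <- renderVelocityCine(truth)
  rec <- reconstructVelocities(encodeAcquisition(cine, spec))
  expect_lt(max(abs(rec@velocity - cine@velocity)), 1e-10)
  expect_false(any(rec@wrapped))

  specM <- smallSpec()   # two coils
  recM <- reconstructVelocities(encodeAcquisition(cine, specM))
  expect_lt(max(abs(recM@velocity - cine@velocity)), 1e-10)
})

test_that("insufficient static region raises an error", {
  spec <- smallSpec(nCoils = 1L)
  cine <- renderVelocityCine(makeMotionModel(spec))
  maps <- combineCoils(encodeAcquisition(cine, spec))
  tiny <- matrix(FALSE, spec@gridSize, spec@gridSize)
  tiny[1, 1:2] <- TRUE
  expect_error(correctEddyPhase(maps, tiny), "insufficient static region")
})
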
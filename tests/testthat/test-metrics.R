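# sample SD computed by the direct formula, independent of stats::sd
sdOracle <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

pulseWave <- function(nF = 70L, dtMs = 3.2, delayMs = 0) {
  t <- (0:(nF - 1)) * dtMs
  tpmcmr:::.activationPulseDot(t - delayMs, nF * dtMs, 0.4)
}

test_that("dispersion of peak motion and strain follow the sample-SD
           formula at the detected timepoints", {
  key <- methods::new("KeyTimepoints", tPeakSystole = 2L, tEndSystole = 3L,
                      tED = 1L)
  reg <- matrix(0, 32, 3)
  reg[, 2] <- rep(c(1, -1), 16)
  wf <- mkWaveforms(reg)
  expect_equal(dispersionOfPeakMotion(wf, key),
               sdOracle(rep(c(1, -1), 16)))    # = sqrt(32/31) = 1.016...
  expect_equal(dispersionOfPeakMotion(mkWaveforms(matrix(2, 32, 3)), key), 0)
  # population convention on request
  expect_equal(dispersionOfPeakMotion(wf, key, sample = FALSE),
               sdOracle(rep(c(1, -1), 16)) * sqrt(31 / 32))

  scm <- matrix(0, 32, 3)
  scm[, 3] <- rep(c(-0.05, -0.15), 16)
  expect_equal(dispersionOfPeakStrain(mkStrainSet(scm), key),
               sdOracle(rep(c(-5, -15), 16)))  # = 5.079... %strain
})

test_that("waveform coherence is 1 for proportional segments and the
           dispersion of +/- global follows the direct formula", {
  g <- pulseWave()
  reg <- outer(seq(0.5, 2, length.out = 32), g)   # positive gains
  coh <- waveformCoherence(mkWaveforms(reg, global = g))
  expect_equal(coh$coherence, 1, tolerance = 1e-12)
  expect_equal(coh$dispersion, 0, tolerance = 1e-12)

  regPM <- rbind(matrix(rep(g, 16), 16, byrow = TRUE),
                 matrix(rep(-g, 16), 16, byrow = TRUE))
  cohPM <- waveformCoherence(mkWaveforms(regPM, global = g))
  expect_equal(cohPM$coherence, 0, tolerance = 1e-12)
  expect_equal(cohPM$dispersion, sdOracle(rep(c(1, -1), each = 16)),
               tolerance = 1e-12)

  # zero-variance segment is excluded and reported
  regZ <- regPM; regZ[5, ] <- 0
  cohZ <- waveformCoherence(mkWaveforms(regZ, global = g))
  expect_equal(cohZ$excluded, 4L)   # 0-based
  expect_equal(length(stats::na.omit(cohZ$r)), 31L)
})

test_that("the dyssynchrony index recovers a single shifted segment with
           the hand-computed delay SD", {
  g <- pulseWave()
  reg <- matrix(rep(g, 32), 32, byrow = TRUE)
  reg[2, ] <- g[((seq_along(g) - 1 - 2) %% length(g)) + 1]  # delayed 2 frames
  dys <- dyssynchronyIndex(mkWaveforms(reg, global = g))
  delays <- c(0, 6.4, rep(0, 30))
  expect_equal(dys$delaysMs[2], 6.4, tolerance = 0.05)
  expect_equal(dys$indexMs, sdOracle(delays), tolerance = 0.05)
  expect_equal(sdOracle(delays), 1.1313708, tolerance = 1e-6)

  # zero imposed delays resolve to (numerically) zero index
  dys0 <- dyssynchronyIndex(mkWaveforms(matrix(rep(g, 32), 32, byrow = TRUE),
                                        global = g))
  expect_lt(dys0$indexMs, 0.5 * 3.2)
  # flat waveforms are excluded
  regF <- matrix(rep(g, 32), 32, byrow = TRUE); regF[7, ] <- 1
  dysF <- dyssynchronyIndex(mkWaveforms(regF, global = g))
  expect_true(6L %in% dysF$excluded)
})

test_that("cyclic resampling is the identity on matching grids and tracks a
           sine closely from 70 to 23 points", {
  set.seed(51)
  y23 <- rnorm(23)
  expect_equal(resampleCurve(y23, 23L), y23, tolerance = 1e-12)

  y70 <- sin(2 * pi * (0:69) / 70)
  r <- resampleCurve(y70, 23L)
  phases <- seq(0, 70, length.out = 24)[1:23]
  expect_lt(max(abs(r - sin(2 * pi * phases / 70))), 1e-3)

  expect_error(resampleCurve(y70, 3L), "at least 4")
})

test_that("peak synchronization aligns circularly shifted copies", {
  y <- -pulseWave()   # strain-like, most negative at the pulse peak
  shifted <- y[((seq_along(y) - 1 + 11) %% length(y)) + 1]
  sync <- synchronizeToPeak(list(y, shifted))
  expect_equal(which.min(sync[[1]]), which.min(sync[[2]]))
  expect_equal(sync[[1]], y)   # reference curve unchanged
  expect_equal(sync[[2]], y)   # a pure shift is fully undone
})

test_that("limits of agreement reproduce hand-computed bias and width", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_equal(limitsOfAgreement(a, a), list(bias = 0, halfWidth = 0, n = 6))
  loa <- limitsOfAgreement(a + c(1, -1, 1, -1, 1, -1), a)
  expect_equal(loa$bias, 0)
  expect_equal(loa$halfWidth, 1.96 * sdOracle(c(1, -1, 1, -1, 1, -1)))
  loa2 <- limitsOfAgreement(a + 2, a)
  expect_equal(loa2$bias, 2)
  expect_equal(loa2$halfWidth, 0)
  expect_error(limitsOfAgreement(1:2, 2:3), "at least 3")
})

test_that("all regional indices are invariant under relabeling of the
           starting segment", {
  run <- defaultRun()
  wf <- run$waveforms$radial
  sc <- run$strain
  key <- run$key
  base <- regionalIndices(wf, sc, key)
  for (shift in c(5L, 17L)) {
    idx <- ((0:31 + shift) %% 32) + 1
    wfS <- wf; wfS@regional <- wf@regional[idx, ]
    wfS@imputed <- wf@imputed[idx, ]
    scS <- sc; scS@sc <- sc@sc[idx, ]; scS@xs <- sc@xs[idx, , ]
    shifted <- regionalIndices(wfS, scS, key)
    expect_equal(shifted, base, tolerance = 1e-10)
  }
})

test_that("global peaks on the phantom match the analytic annulus-mean
           radial velocity within 5 % and land in systole", {
  run <- defaultRun()
  truth <- defaultTruth()
  spec <- truth@spec
  pk <- globalPeaks(run$waveforms$radial, run$strain)
  # analytic mask-mean radial velocity (contraction positive):
  # a'(t) / (rEndo(t) + rEpi(t)) in mm/ms over the deforming annulus
  rMid <- (spec@rEndoMm + spec@rEpiMm) / 2
  aPeak <- rMid^2 * (1 - (1 - spec@contractionAmplitude)^2)
  t <- (0:(spec@nFrames - 1)) * spec@frameMs
  Tms <- spec@nFrames * spec@frameMs
  aDot <- aPeak * tpmcmr:::.activationPulseDot(t, Tms, spec@systoleFraction)
  aT <- aPeak * tpmcmr:::.activationPulse(t, Tms, spec@systoleFraction)
  vBar <- 100 * aDot / (2 * (sqrt(spec@rEndoMm^2 - aT) +
                               sqrt(spec@rEpiMm^2 - aT))) * 2
  expect_equal(pk$radialMaxCmS, max(vBar), tolerance = 0.05)
  expect_equal(pk$radialMinCmS, min(vBar), tolerance = 0.05)
  # contraction-positive peak occurs during systole (first 40 % of cycle)
  expect_lt(pk$tRadialMax, 0.4 * spec@nFrames)
  expect_gt(pk$tRadialMin, pk$tRadialMax)
  # zero-motion waveforms give zero peaks
  z <- mkWaveforms(matrix(0, 32, 5))
  pz <- globalPeaks(z, mkStrainSet(matrix(0, 32, 5)))
  expect_equal(c(pz$radialMaxCmS, pz$radialMinCmS, pz$peakScPercent),
               c(0, 0, 0))
})

test_that("the t-test wrapper reports the expected group difference", {
  set.seed(52)
  a <- rnorm(8, mean = 2.2, sd = 0.2)
  b <- rnorm(10, mean = 1.4, sd = 0.3)
  ht <- compareGroups(a, b)
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 0.05)
})
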
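test_that("bulk-motion subtraction removes a uniform field and leaves a
           zero-mean field untouched", {
  n <- 12L
  model <- mkGridModel(n, 1, nFrames = 2L)
  cine <- mkUniformCine(rbind(c(1.5, -0.6, 0.9), c(-0.2, 0.4, 0.9)), n = n)
  out <- subtractBulkMotion(cine, model)
  expect_equal(max(abs(out@velocity[, , , 1:2])), 0)
  expect_equal(out@velocity[, , , 3], cine@velocity[, , , 3])

  set.seed(41)
  cine2 <- mkUniformCine(matrix(0, 2, 3), n = n)
  vx <- matrix(rnorm(n * n), n, n); vx <- vx - mean(vx)
  vy <- matrix(rnorm(n * n), n, n); vy <- vy - mean(vy)
  for (f in 1:2) {
    cine2@velocity[f, , , 1] <- vx
    cine2@velocity[f, , , 2] <- vy
  }
  out2 <- subtractBulkMotion(cine2, model)
  expect_equal(out2@velocity, cine2@velocity, tolerance = 1e-12)
})

test_that("cardiopolar decomposition reports contraction as positive radial
           motion and preserves in-plane speed", {
  n <- 8L
  model <- mkGridModel(n, 1)
  # velocity (-1, 0): pixels on the +x axis move towards the centre
  cine <- mkUniformCine(matrix(c(-1, 0, 0), 1), n = n)
  polar <- toCardiopolar(cine, model)
  co <- tpmcmr:::.pixelCoords(n, 1)
  ix <- which(co > 0)
  iy0 <- which.min(abs(co))
  # pick the pixel closest to the +x axis
  th <- atan2(co[iy0], co[max(ix)])
  expect_equal(polar@radial[1, iy0, max(ix)], cos(th), tolerance = 1e-12)
  expect_equal(polar@tangential[1, iy0, max(ix)], sin(th), tolerance = 1e-12)

  set.seed(42)
  cineR <- mkUniformCine(matrix(0, 1, 3), n = n)
  cineR@velocity[1, , , 1] <- rnorm(n * n)
  cineR@velocity[1, , , 2] <- rnorm(n * n)
  pR <- toCardiopolar(cineR, model)
  speed2 <- cineR@velocity[1, , , 1]^2 + cineR@velocity[1, , , 2]^2
  expect_equal(pR@radial[1, , ]^2 + pR@tangential[1, , ]^2, speed2,
               tolerance = 1e-12)
})

test_that("a rigid-rotation phantom has no radial velocity anywhere in the
           myocardium", {
  spec <- smallSpec(contractionAmplitude = 0, rotationAmplitudeRad = 0.15,
                    longitudinalAmplitudeCmS = 0)
  truth <- makeMotionModel(spec)
  cine <- renderVelocityCine(truth)
  ann <- phantomAnnotations(truth)
  polys <- interpolateContours(ann, spec@nFrames)
  model <- buildSegmentModel(polys, ann, spec@gridSize,
                             spec@fovMm / spec@gridSize)
  # decomposition applied to the rendered field directly: a rotation about
  # the LV centre is purely tangential at every pixel centre
  polar <- toCardiopolar(cine, model)
  expect_lt(max(abs(polar@radial[model@mask])), 1e-9)
})

test_that("waveform extraction: constants propagate, segment labels map to
           their own rows, global is the mask mean", {
  n <- 16L
  model <- mkGridModel(n, 1)
  cine <- mkUniformCine(matrix(c(0, 0, 0), 1), n = n)
  polar <- toCardiopolar(cine, model)
  polar@radial[1, , ] <- 3.25
  wf <- extractWaveforms(polar, model, "radial")
  expect_equal(wf@global, 3.25)
  expect_equal(as.numeric(wf@regional), rep(3.25, 32))

  # value = segment index
  polar@radial[1, , ] <- model@segmentMap[1, , ]
  wf2 <- extractWaveforms(polar, model, "radial")
  expect_equal(as.numeric(wf2@regional), as.numeric(0:31))
  expect_equal(wf2@global, mean(model@segmentMap[1, , ]))
})

test_that("empty segments carry the nearest frame's value and are flagged", {
  n <- 16L
  model <- mkGridModel(n, 1, nFrames = 3L)
  # remove segment 0 pixels from the mask at frame 2
  sm <- model@segmentMap
  drop <- sm[2, , ] == 0L
  m <- model@mask; m[2, , ][drop] <- FALSE
  sm[2, , ][drop] <- NA_integer_
  model@mask <- m; model@segmentMap <- sm
  cine <- mkUniformCine(matrix(0, 3, 3), n = n)
  polar <- toCardiopolar(cine, model)
  for (f in 1:3) polar@radial[f, , ] <- f
  wf <- extractWaveforms(polar, model, "radial")
  expect_true(wf@imputed[1, 2])
  expect_equal(sum(wf@imputed), 1L)
  expect_equal(wf@regional[1, ], c(1, 1, 3))  # carried from frame 1
})

test_that("key timepoints: phantom end-systole at the minimum-area frame,
           ramps and ties resolve as specified", {
  run <- defaultRun()
  spec <- defaultTruth()@spec
  # analytic activation peak (minimum lumen area) at 20 % of the cycle
  fPeak <- round(0.2 * spec@nFrames) + 1
  expect_lte(abs(run$key@tEndSystole - fPeak), 1)
  expect_equal(run$key@tED, 1L)

  ramp <- mkWaveforms(matrix(rep(seq(0, 1, length.out = 10), each = 32),
                             32, 10))
  kt <- detectKeyTimepoints(ramp, rep(2, 10), tED = 1L)
  expect_equal(kt@tPeakSystole, 10L)
  expect_equal(kt@tEndSystole, 1L)   # constant area: earliest frame wins
})

test_that("temporal alignment recovers identity and constructed stretch
           factors, and averaging two identical runs is the identity", {
  run1 <- cachedFixture("smallRun", runForSpec(smallSpec(gridSize = 64L,
                                                         nFrames = 40L)))
  aa <- alignAndAverage(run1, run1)
  expect_equal(aa$stretch, 1.0)
  expect_equal(aa$correlation, 1.0, tolerance = 1e-12)
  expect_equal(aa$run$waveforms$radial@global, run1$waveforms$radial@global,
               tolerance = 1e-12)
  expect_equal(aa$run$strain@sc, run1$strain@sc, tolerance = 1e-12)

  # run 2 constructed by resampling run 1 onto a compressed cycle
  s <- 0.90
  T1 <- length(run1$timeMs) * run1$frameMs
  run2 <- run1
  for (nm in names(run1$waveforms)) {
    w <- run1$waveforms[[nm]]
    f <- tpmcmr:::.periodicSplineFun(run1$timeMs, w@global, T1)
    run2$waveforms[[nm]]@global <- f((run1$timeMs / s) %% T1)
    run2$waveforms[[nm]]@regional <- t(apply(w@regional, 1, function(y) {
      g <- tpmcmr:::.periodicSplineFun(run1$timeMs, y, T1)
      g((run1$timeMs / s) %% T1)
    }))
  }
  aa2 <- alignAndAverage(run1, run2)
  expect_equal(aa2$stretch, 0.90, tolerance = 0.0051)

  # inconsistent acquisitions trigger a warning
  runN <- run1
  set.seed(43)
  runN$waveforms$radial@global <- rnorm(length(run1$timeMs))
  expect_warning(alignAndAverage(run1, runN), "inconsistent")
})
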
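# Synthetic phantom: analytic scene construction, rendering, drift.

test_that("makeScene builds exact analytic geometry", {
  sc <- makeScene(70, 0)
  expect_equal(trueAlpha(sc), 70)
  # iliac margin exactly vertical at zero inclination
  expect_equal(sc@iliacSegment[1, 2], sc@iliacSegment[2, 2])
  expect_equal(GrafAngle:::segmentAngleDeg(sc@iliacSegment, sc@roofSegment),
               70, tolerance = 1e-9)

  # perpendicular case: roof exactly horizontal
  sc90 <- makeScene(90, 0)
  expect_lt(abs(sc90@roofSegment[1, 1] - sc90@roofSegment[2, 1]), 1e-9)

  # recomputing the angle from stored endpoints returns the input
  sc55 <- makeScene(55, 4)
  expect_equal(GrafAngle:::segmentAngleDeg(sc55@iliacSegment,
                                           sc55@roofSegment), 55,
               tolerance = 1e-9)
})

test_that("scene invariants hold over a parameter grid", {
  for (alpha in c(35, 48.5, 60, 70, 82, 89.9)) {
    for (incl in c(-12, -4, 0, 3.3, 9)) {
      sc <- makeScene(alpha, incl)
      expect_lt(abs(GrafAngle:::segmentAngleDeg(sc@iliacSegment,
                                                sc@roofSegment) - alpha),
                1e-6)
      # rim is the iliac segment's caudal end
      expect_lt(sqrt(sum((sc@iliacSegment[2, ] - rimPoint(sc))^2)), 1)
      # iliac direction makes angle `incl` with the vertical axis
      v <- sc@iliacSegment[2, ] - sc@iliacSegment[1, ]
      ang <- atan2(v[2], v[1]) * 180 / pi
      expect_equal(ang, incl, tolerance = 1e-9)
      # rim lies on the roof's supporting line
      roofFit <- fitLineTLS(sc@roofSegment)
      expect_lt(abs(drop(linePointDistance(roofFit, rbind(rimPoint(sc))))),
                1e-6)
    }
  }
})

test_that("makeScene rejects out-of-range parameters", {
  expect_error(makeScene(20, 0), "30")
  expect_error(makeScene(95, 0), "30")
  expect_error(makeScene(70, 31), "inclination")
})

test_that("noiseless rendering paints exactly the rasterized segments", {
  sc <- makeScene(70, 0)
  fr <- renderFrame(sc, noiselessConfig(), seed = 3)
  m <- frameData(fr$frame)
  mask <- GrafAngle:::sceneRidgeMask(sc)
  expect_true(all(m[mask] == 220))
  expect_true(all(m[!mask] == 20))
})

test_that("rendering is deterministic in (scene, noise, seed)", {
  sc <- makeScene(64, -2)
  a <- renderFrame(sc, noiseConfig(), seed = 42)
  b <- renderFrame(sc, noiseConfig(), seed = 42)
  expect_identical(frameData(a$frame), frameData(b$frame))
  c <- renderFrame(sc, noiseConfig(), seed = 43)
  expect_false(identical(frameData(a$frame), frameData(c$frame)))
})

test_that("bone ridge stays brighter than background under speckle", {
  sc <- makeScene(70, 0)
  fr <- renderFrame(sc, noiseConfig(speckleScale = 0.2, blurSigma = 0,
                                    shadowAttenuation = 0), seed = 42)
  m <- frameData(fr$frame)
  mask <- GrafAngle:::sceneRidgeMask(sc)
  expect_gt(mean(m[mask]), mean(m[!mask]))
})

test_that("renderFrame demands an explicit seed", {
  expect_error(renderFrame(makeScene(70, 0), noiseConfig()), "seed")
})

test_that("drift accumulates and off-plane frames are flagged", {
  sc <- makeScene(70, 1)
  seq0 <- renderSequence(sc, 3, driftModel(), noiselessConfig(), seed = 5)
  expect_identical(frameData(seq0$frames[[1]]), frameData(seq0$frames[[3]]))
  expect_true(all(vapply(seq0$truths, isDiagnostic, logical(1))))

  seq1 <- renderSequence(sc, 5, driftModel(rotationPerFrame = 0.5),
                         noiselessConfig(), seed = 5)
  expect_equal(trueInclination(seq1$truths[[5]]),
               trueInclination(seq1$truths[[1]]) + 2.0)
  expect_equal(trueAlpha(seq1$truths[[5]]), 70)

  seq2 <- renderSequence(sc, 4, driftModel(offplaneFrames = 3L),
                         noiseConfig(), seed = 5)
  diag <- vapply(seq2$truths, isDiagnostic, logical(1))
  expect_identical(which(!diag), 3L)

  expect_error(renderSequence(sc, 3, driftModel(offplaneFrames = 9L),
                              noiseConfig(), seed = 1), "offplane")
})

test_that("translation drift moves the ground-truth landmarks", {
  sc <- makeScene(70, 0)
  sq <- renderSequence(sc, 3, driftModel(translationPerFrame = c(1, -2)),
                       noiselessConfig(), seed = 2)
  expect_equal(rimPoint(sq$truths[[3]]), rimPoint(sq$truths[[1]]) + c(2, -4))
})

test_that("rendering is rotation-equivariant about the rim", {
  delta <- 4
  sc0 <- makeScene(70, 0)
  scd <- makeScene(70, delta)
  nz <- blurOnlyConfig()
  f0 <- frameData(renderFrame(sc0, nz, seed = 1)$frame)
  fd <- frameData(renderFrame(scd, nz, seed = 1)$frame)
  fr <- rotateFrameNN(f0, delta, center = rimPoint(sc0), fill = 20)
  # compare away from the canvas border, where rotation leaves the frame
  inner <- 20:236
  expect_lt(mean(abs(fd[inner, inner] - fr[inner, inner])), 2)
})
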
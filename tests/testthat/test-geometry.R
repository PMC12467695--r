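# Measurement geometry: preprocessing, ridge extraction, screening, roof
# fit, and the orchestrated alpha measurement.

test_that("preprocessFrame preserves shape, range, and constants", {
  const <- matrix(77, 32, 32)
  expect_equal(preprocessFrame(const), const)
  fr <- renderPhantom(70, 0, blurOnlyConfig(), seed = 1)
  out <- preprocessFrame(frameData(fr$frame))
  expect_identical(dim(out), dim(frameData(fr$frame)))
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
})

test_that("preprocessFrame suppresses salt noise and is near-idempotent", {
  fr <- renderPhantom(70, 0, blurOnlyConfig(), seed = 1)
  clean <- frameData(fr$frame)
  set.seed(5)
  salted <- clean
  idx <- sample(length(salted), round(0.01 * length(salted)))
  salted[idx] <- 255
  rec <- preprocessFrame(salted)
  expect_lt(mean(abs(rec - clean)), 1.5)
  once <- preprocessFrame(clean)
  twice <- preprocessFrame(once)
  expect_lt(mean(abs(twice - once)), 1)
})

test_that("extractLocalMaxima finds strict per-scanline maxima", {
  one <- matrix(c(0, 1, 3, 1, 0), nrow = 1)
  ps <- extractLocalMaxima(one, "rows", minSeparation = 1)
  expect_identical(unname(ps@coords), cbind(1, 3))
  expect_identical(ps@intensities, 3)

  mono <- matrix(0:4, nrow = 1)
  expect_identical(nrow(extractLocalMaxima(mono, "rows")@coords), 0L)

  # plateau counts once, at its center, never in its interior
  plat <- matrix(c(0, 0, 7, 7, 7, 0, 0), nrow = 1)
  pp <- extractLocalMaxima(plat, "rows")
  expect_identical(unname(pp@coords), cbind(1, 4))

  expect_identical(nrow(extractLocalMaxima(matrix(5, 10, 10))@coords), 0L)

  # column scan transposes the role of the axes
  two <- matrix(c(0, 1, 3, 1, 0), ncol = 1)
  pc <- extractLocalMaxima(two, "cols", minSeparation = 1)
  expect_identical(unname(pc@coords), cbind(3, 1))
})

test_that("minSeparation suppresses close secondary maxima", {
  v <- matrix(c(0, 5, 0, 4, 0, 0, 0, 6, 0), nrow = 1)
  ps <- extractLocalMaxima(v, "rows", minSeparation = 3)
  # peaks at 2 (5), 4 (4), 8 (6): the 4 at offset 4 is within 3 px of the
  # stronger 5 at offset 2 and must be suppressed
  expect_setequal(ps@coords[, 2], c(2, 8))
})

test_that("ridge maxima on a clean frame lie on the true ridges", {
  sc <- makeScene(70, 0)
  fr <- renderFrame(sc, blurOnlyConfig(), seed = 2)
  pp <- preprocessFrame(frameData(fr$frame))
  ps <- extractLocalMaxima(pp, "rows")
  sp <- screenPeaks(ps, k = 2, minSupport = 5, frame = pp)
  mask <- GrafAngle:::sceneRidgeMask(sc)
  ridgePix <- which(mask, arr.ind = TRUE)
  near <- vapply(seq_len(nrow(sp@coords)), function(i) {
    d2 <- (ridgePix[, 1] - sp@coords[i, 1])^2 +
          (ridgePix[, 2] - sp@coords[i, 2])^2
    sqrt(min(d2))
  }, numeric(1))
  expect_gte(mean(near <= 1), 0.9)
})

test_that("screenPeaks retains exactly the points above the threshold", {
  ps <- new("PointSet", coords = cbind(1:5, 1),
            intensities = c(10, 12, 11, 200, 210))
  kept <- screenPeaks(ps, threshold = 101.97)
  expect_identical(kept@intensities, c(200, 210))
  # threshold 0 is the identity
  expect_identical(screenPeaks(ps, threshold = 0)@intensities,
                   ps@intensities)
  # empty in, empty out
  emptyPs <- new("PointSet", coords = cbind(numeric(0), numeric(0)),
                 intensities = numeric(0))
  expect_identical(nrow(screenPeaks(emptyPs)@coords), 0L)
})

test_that("raising the screening threshold never adds points", {
  set.seed(31)
  ps <- new("PointSet", coords = cbind(sample(100, 60, TRUE),
                                       sample(100, 60, TRUE)),
            intensities = runif(60, 0, 255))
  counts <- vapply(seq(0, 260, by = 20), function(thr)
    length(screenPeaks(ps, threshold = thr)@intensities), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("auto threshold keeps ridge peaks against a noise floor", {
  set.seed(8)
  ints <- c(runif(300, 15, 40), runif(30, 140, 180))
  ps <- new("PointSet", coords = cbind(seq_along(ints), 1),
            intensities = ints)
  kept <- screenPeaks(ps, k = 2)
  expect_true(all(kept@intensities >= 140))
  expect_identical(length(kept@intensities), 30L)
})

test_that("fitRoofLine recovers the roof direction", {
  sc <- makeScene(70, 0)
  trueRoofTheta <- fitLineTLS(sc@roofSegment)@theta

  prep <- function(frame) {
    pp <- preprocessFrame(frame)
    sp <- screenPeaks(extractLocalMaxima(pp, "rows"), k = 2,
                      minSupport = 5, frame = pp)
    list(pp = pp, sp = sp)
  }
  run <- function(noise, seed, mode) {
    fr <- renderFrame(sc, noise, seed = seed)
    det <- detectLandmarks(fr$frame)
    x <- prep(fr$frame)
    iliac <- fitLineTLS(x$sp@coords[x$sp@coords[, 1] <= 144, , drop = FALSE])
    base <- constructBaseline(iliac, rimPoint(sc))
    fitRoofLine(x$pp, boundingBox(det[[1]]), boundingBox(det[[2]]), x$sp,
                baseline = base, mode = mode)
  }
  clean <- run(noiselessConfig(), 1, "dynamic")
  expect_lt(GrafAngle:::thetaSeparationDeg(clean@theta, trueRoofTheta), 0.5)
  noisy <- run(noiseConfig(), 7, "dynamic")
  expect_lt(GrafAngle:::thetaSeparationDeg(noisy@theta, trueRoofTheta), 2)
  cleanStatic <- run(noiselessConfig(), 1, "static")
  expect_lt(GrafAngle:::thetaSeparationDeg(cleanStatic@theta,
                                           trueRoofTheta), 1)

  # a region holding only the baseline-parallel ridge is a roof failure
  fr <- renderFrame(sc, noiselessConfig(), seed = 1)
  x <- prep(fr$frame)
  base <- constructBaseline(lineModel(0, 110), rimPoint(sc))
  upperBox <- c(40, 98, 80, 122)   # iliac-only region
  expect_null(fitRoofLine(x$pp, upperBox, upperBox, x$sp, baseline = base))
})

test_that("measureAlpha hits the reference on clean and noisy frames", {
  fr <- renderPhantom(70, 0, noiselessConfig(), seed = 1)
  det <- detectLandmarks(fr$frame)
  m <- measureAlpha(fr$frame, det, mode = "dynamic")
  expect_false(isFailure(m))
  expect_lt(abs(alphaDeg(m) - 70), 0.5)
  expect_lt(abs(inclinationDeg(m)), 0.5)

  frN <- renderPhantom(70, 0, noiseConfig(), seed = 11)
  detN <- detectLandmarks(frN$frame)
  mS <- measureAlpha(frN$frame, detN, mode = "static")
  expect_false(isFailure(mS))
  expect_lte(abs(alphaDeg(mS) - 70), 3)
})

test_that("measureAlpha reports inclination against generator truth", {
  fr <- renderPhantom(70, 4, noiselessConfig(), seed = 2)
  m <- measureAlpha(fr$frame, detectLandmarks(fr$frame), mode = "dynamic")
  expect_lt(abs(inclinationDeg(m) - 4), 0.5)
})

test_that("missing landmarks give reason-coded failures", {
  fr <- renderPhantom(70, 0, noiselessConfig(), seed = 1)
  det <- detectLandmarks(fr$frame)
  onlyLow <- Filter(function(d) landmarkLabel(d) == "ilium_lower_limb", det)
  onlyRim <- Filter(function(d) landmarkLabel(d) == "acetabular_rim", det)
  f1 <- measureAlpha(fr$frame, onlyLow, mode = "dynamic")
  expect_true(isFailure(f1))
  expect_identical(f1@status, "rim_not_detected")
  f2 <- measureAlpha(fr$frame, onlyRim, mode = "dynamic")
  expect_identical(f2@status, "lower_limb_not_detected")
  expect_true(is.na(alphaDeg(f2)))
})

test_that("alpha is recomputable from the stored line models", {
  for (seed in 1:3) {
    fr <- renderPhantom(68, 1, noiseConfig(), seed = seed)
    m <- measureAlpha(fr$frame, detectLandmarks(fr$frame), mode = "dynamic")
    expect_false(isFailure(m))
    expect_equal(alphaDeg(m), angleBetween(m@baseline, m@roofLine),
                 tolerance = 1e-9)
    expect_equal(abs(inclinationDeg(m)),
                 abs(iliacInclination(m@iliacLine)), tolerance = 1e-9)
    expect_identical(m@baseline@theta, m@iliacLine@theta)
  }
})

test_that("measurement is rotation-equivariant on clean frames", {
  m0 <- local({
    fr <- renderPhantom(70, 0, blurOnlyConfig(), seed = 1)
    measureAlpha(fr$frame, detectLandmarks(fr$frame), mode = "dynamic")
  })
  for (delta in c(-6, 3, 8)) {
    fr <- renderPhantom(70, delta, blurOnlyConfig(), seed = 1)
    m <- measureAlpha(fr$frame, detectLandmarks(fr$frame), mode = "dynamic")
    expect_false(isFailure(m))
    expect_lt(abs(inclinationDeg(m) - (inclinationDeg(m0) + delta)), 0.5)
    expect_lt(abs(alphaDeg(m) - alphaDeg(m0)), 0.5)
  }
})

test_that("alpha is invariant to global intensity scaling", {
  fr <- renderPhantom(70, 2, noiseConfig(), seed = 6)
  m <- frameData(fr$frame)
  det <- detectLandmarks(m)
  a1 <- alphaDeg(measureAlpha(m, det, mode = "dynamic"))
  for (s in c(0.55, 0.8)) {
    det_s <- detectLandmarks(m * s)
    a2 <- alphaDeg(measureAlpha(m * s, det_s, mode = "dynamic"))
    expect_equal(a2, a1, tolerance = 1e-6)
  }
})
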
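test_that("arctangent retrieval maps the canonical channel patterns to their phases", {
  one <- matrix(1, 8, 8); half <- matrix(0.5, 8, 8); zero <- matrix(0, 8, 8)
  p0 <- wrappedPhase(HologramSet(list(ccd1 = one, ccd2 = zero,
    ccd3 = half, ccd4 = half)))
  expect_equal(phaseValues(p0), zero)
  p90 <- wrappedPhase(HologramSet(list(ccd1 = half, ccd2 = half,
    ccd3 = one, ccd4 = zero)))
  expect_equal(phaseValues(p90), zero + pi / 2)
  expect_true(isWrapped(p90))
})

test_that("pixels without fringe modulation are masked and zeroed", {
  one <- matrix(1, 8, 8)
  one[1, 1] <- 2  # give the set a nonzero max modulation elsewhere
  h <- HologramSet(list(ccd1 = one, ccd2 = matrix(1, 8, 8),
    ccd3 = matrix(1, 8, 8), ccd4 = matrix(1, 8, 8)))
  p <- wrappedPhase(h)
  m <- validityMask(p)
  expect_false(m[5, 5])
  expect_true(m[1, 1])
  expect_equal(phaseValues(p)[5, 5], 0)
})

test_that("simulate -> retrieve round-trips the wrapped truth at machine precision", {
  set.seed(9)
  for (i in 1:5) {
    s <- randomSmoothSample(c(24, 24), maxPhase = 4)
    off <- runif(1, -pi, pi)
    cfg <- OpticalConfig(dims = c(24, 24), armPhaseOffset = off,
      amplitudeObject = 0.8, amplitudeReference = 1.2)
    w <- phaseValues(wrappedPhase(closedFormIntensities(s, cfg)))
    expect_lt(maxAbs(wrapToPi(w - (truthPhase(s) + off))), 1e-10)
  }
})

test_that("calibration subtraction removes the arm offset and wraps correctly", {
  set.seed(12)
  s <- randomSmoothSample(c(24, 24), maxPhase = 2)
  cfg <- OpticalConfig(dims = c(24, 24), armPhaseOffset = 1.0)
  meas <- wrappedPhase(closedFormIntensities(s, cfg))
  blank <- SampleField(transmission = matrix(1 + 0i, 24, 24),
    pixelSize = 0.345, truthPhase = matrix(0, 24, 24),
    truthThickness = matrix(0, 24, 24), nSample = 1, nMedium = 1)
  calib <- wrappedPhase(closedFormIntensities(blank, cfg))
  # raw retrieval is biased by the arm offset; compensation removes it
  expect_gt(maxAbs(wrapToPi(phaseValues(meas) - truthPhase(s))), 0.5)
  comp <- subtractCalibration(meas, calib)
  expect_lt(maxAbs(wrapToPi(phaseValues(comp) - truthPhase(s))), 1e-10)
  # identical maps cancel; wrapping arithmetic is modular
  zero <- subtractCalibration(meas, meas)
  expect_equal(maxAbs(phaseValues(zero)), 0)
  a <- PhaseMap(matrix(3.0, 2, 2)); b <- PhaseMap(matrix(-3.0, 2, 2))
  expect_equal(phaseValues(subtractCalibration(a, b))[1, 1],
    6.0 - 2 * pi)
  expect_error(subtractCalibration(a, PhaseMap(matrix(0, 3, 3))),
    "dims")
})

test_that("least-squares unwrapping recovers residue-free fields up to a constant", {
  # analytic ramp
  ramp <- outer(rep(1, 48), 0.3 * (1:64))
  u <- unwrapPhase(PhaseMap(wrapToPi(ramp)))
  expect_equal(residueCount(u), 0)
  d <- phaseValues(u) - ramp
  expect_lt(max(d) - min(d), 1e-6)
  expect_false(isWrapped(u))
  # already-unwrapped smooth field: unchanged up to a constant
  set.seed(14)
  sm <- smoothField(c(32, 32), scale = 2.5)
  u2 <- unwrapPhase(PhaseMap(wrapToPi(sm)))
  d2 <- phaseValues(u2) - sm
  expect_lt(max(d2) - min(d2), 1e-6)
})

test_that("a wrapped thick-bead dome unwraps to the true profile", {
  px <- 0.345
  bead <- beadField(beadSpec(20), nMedium = 1.51, dims = c(192, 192),
    pixelSize = px, wavelength = 0.532)
  truth <- truthPhase(bead)
  expect_gt(maxAbs(truth), pi)  # genuinely wrapped input
  u <- unwrapPhase(PhaseMap(wrapToPi(truth), pixelSize = px))
  expect_equal(residueCount(u), 0)
  d <- phaseValues(u) - truth
  expect_lt(sqrt(mean((d - mean(d))^2)), 1e-3)
})

test_that("phase-to-thickness follows the OPD formula and its scalings", {
  expect_equal(round(phaseToThickness(2.35, 0.532, 1.49, 1.51), 2),
    9.95)
  expect_equal(round(phaseToThickness(2.36, 0.532, 1.49, 1.51), 2),
    9.99)
  expect_equal(phaseToThickness(0, 0.532, 1.49, 1.51), 0)
  # linear in phase and wavelength, inverse in index contrast
  expect_equal(phaseToThickness(2, 0.5, 1.5, 1.0),
    2 * phaseToThickness(1, 0.5, 1.5, 1.0))
  expect_equal(phaseToThickness(1, 1.0, 1.5, 1.0),
    2 * phaseToThickness(1, 0.5, 1.5, 1.0))
  expect_equal(phaseToThickness(1, 0.5, 1.25, 1.0),
    2 * phaseToThickness(1, 0.5, 1.5, 1.0))
  expect_error(phaseToThickness(1, 0.5, 1.5, 1.5), "undefined")
  # map conversion: signed contrast with signed phase gives positive
  # heights for a bead in higher-index oil
  pm <- PhaseMap(matrix(-2.362, 4, 4), wrapped = FALSE,
    pixelSize = 0.345)
  tm <- phaseToThickness(pm, 0.532, 1.49, 1.51)
  expect_gt(min(thicknessValues(tm)), 0)
  expect_equal(tm@nSample, 1.49)
})

test_that("theoretical resolution is lambda over twice the aperture", {
  expect_equal(theoreticalResolution(0.532, 0.25), 1.064)
  expect_equal(theoreticalResolution(0, 0.25), 0)
  expect_equal(theoreticalResolution(0.532, 0.5),
    theoreticalResolution(0.532, 0.25) / 2)
  expect_error(theoreticalResolution(0.532, 0))
})

test_that("the noise-free pipeline recovers a chart step exactly", {
  cfg <- OpticalConfig(dims = c(256, 256), armPhaseOffset = 0.4)
  px <- objectPixelSize(cfg)
  chart <- usafPhaseTarget(list(c(8, 1)), height = 0.2138,
    dims = c(256, 256), pixelSize = px)
  holos <- closedFormIntensities(chart, cfg)
  calib <- closedFormIntensities(emptyField(c(256, 256), px), cfg)
  rec <- reconstructHolograms(holos, calib, nSample = 1.52,
    nMedium = 1.0)
  step <- stepHeight(rec$thickness, usafFeatureROI(chart, 8, 1),
    usafSubstrateROI(chart, 8, 1))
  expect_equal(step, 0.2138, tolerance = 1e-6)
  expect_warning(
    reconstructHolograms(holos, calib = NULL, nSample = 1.52,
      nMedium = 1.0), "calibration")
})
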
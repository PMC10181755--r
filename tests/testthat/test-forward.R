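test_that("closed-form intensities reproduce the canonical phase-shift patterns", {
  z <- matrix(0, 8, 8)
  cfg <- OpticalConfig(dims = c(8, 8))
  flat <- SampleField(transmission = z + (1 + 0i), pixelSize = 0.345,
    truthPhase = z, truthThickness = z, nSample = 1, nMedium = 1)
  h <- hologramImages(closedFormIntensities(flat, cfg))
  expect_equal(h$ccd1, z + 1)
  expect_equal(h$ccd2, z)
  expect_equal(h$ccd3, z + 0.5)
  expect_equal(h$ccd4, z + 0.5)

  quarter <- SampleField(transmission = exp(1i * (z + pi / 2)),
    pixelSize = 0.345, truthPhase = z + pi / 2, truthThickness = z,
    nSample = 1, nMedium = 1)
  h <- hologramImages(closedFormIntensities(quarter, cfg))
  expect_equal(h$ccd1, z + 0.5)
  expect_equal(h$ccd2, z + 0.5)
  expect_equal(h$ccd3, z + 1)
  expect_equal(h$ccd4, z)

  expect_error(closedFormIntensities(flat,
    OpticalConfig(dims = c(16, 16))), "dims")
})

test_that("Jones-chain propagation equals the closed form on random samples", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    s <- randomSmoothSample(c(12, 12), maxPhase = runif(1, 0.5, 4))
    cfg <- OpticalConfig(dims = c(12, 12),
      amplitudeObject = runif(1, 0.5, 1.5),
      amplitudeReference = runif(1, 0.5, 1.5),
      armPhaseOffset = runif(1, -pi, pi))
    a <- hologramImages(closedFormIntensities(s, cfg))
    b <- hologramImages(propagateSystem(s, cfg))
    scale <- max(unlist(lapply(a, max)))
    worst <- max(worst,
      max(mapply(function(x, y) maxAbs(x - y), a, b)) / scale)
  }
  expect_lt(worst, 1e-12)
})

test_that("reference-only and uniform scenes behave as the closed form dictates", {
  z <- matrix(0, 8, 8)
  cfg <- OpticalConfig(dims = c(8, 8), amplitudeReference = 1.2)
  dark <- SampleField(transmission = z + 0i, pixelSize = 0.345,
    truthPhase = z, truthThickness = z, nSample = 1, nMedium = 1)
  h <- hologramImages(propagateSystem(dark, cfg))
  for (im in h) expect_equal(im, z + 0.25 * 1.2^2)
  # uniform sample -> spatially constant channels
  u <- SampleField(transmission = 0.7 * exp(1i * (z + 0.9)),
    pixelSize = 0.345, truthPhase = z + 0.9, truthThickness = z,
    nSample = 1, nMedium = 1)
  for (im in hologramImages(propagateSystem(u, cfg)))
    expect_equal(maxAbs(im - im[1, 1]), 0, tolerance = 1e-14)
})

test_that("channel sums and fringe modulation obey the closed-form bounds", {
  set.seed(5)
  s <- randomSmoothSample(c(32, 32), maxPhase = 3)
  cfg <- OpticalConfig(dims = c(32, 32), amplitudeObject = 0.9,
    amplitudeReference = 1.1, armPhaseOffset = 0.3)
  h <- hologramImages(closedFormIntensities(s, cfg))
  # I1 + I2 = I3 + I4 pointwise for noise-free aligned sets
  expect_lt(maxAbs(h$ccd1 + h$ccd2 - h$ccd3 - h$ccd4), 1e-14)
  # |I1 - I2| <= alpha * A_O * A_R, equality where cos == +/-1
  bound <- Mod(transmission(s)) * 0.9 * 1.1
  expect_true(all(abs(h$ccd1 - h$ccd2) <= bound + 1e-12))
})

test_that("the coherent pupil passes DC, preserves wide structure and kills sub-resolution bars", {
  z <- matrix(0, 64, 64)
  dc <- SampleField(transmission = z + (0.8 + 0i), pixelSize = 0.345,
    truthPhase = z, truthThickness = z, nSample = 1, nMedium = 1)
  cfg <- OpticalConfig(dims = c(64, 64), pupilEnabled = TRUE)
  expect_lt(maxAbs(transmission(applyPupil(dc, cfg)) -
    transmission(dc)), 1e-12)

  # cutoff beyond the sampling Nyquist: field unchanged
  s <- randomSmoothSample(c(32, 32))
  cfgWide <- OpticalConfig(dims = c(32, 32), na = 1, wavelength = 0.2,
    pupilEnabled = TRUE)
  expect_lt(maxAbs(transmission(applyPupil(s, cfgWide)) -
    transmission(s)), 1e-12)

  # a bar pattern below the diffraction limit loses its modulation:
  # 0.69 um lines (period exactly 4 px so no harmonic aliases into the
  # 0.47 cycles/um passband)
  px <- 0.345
  xs <- (seq_len(256) - 0.5) * px
  bars <- outer(rep(1, 64), as.numeric((xs %% 1.38) < 0.69))
  sf <- SampleField(transmission = exp(1i * bars), pixelSize = px,
    truthPhase = bars, truthThickness = bars * 0, nSample = 1,
    nMedium = 1)
  cfgNA <- OpticalConfig(dims = c(64, 256), pupilEnabled = TRUE)
  filt <- Arg(transmission(applyPupil(sf, cfgNA)))
  mid <- filt[32, 30:226]
  expect_lt(diff(range(mid)), 0.1 * diff(range(bars)))
})

test_that("camera corruption is the identity when disabled and deterministic when seeded", {
  set.seed(2)
  s <- randomSmoothSample(c(32, 32))
  cfg <- OpticalConfig(dims = c(32, 32))
  h <- closedFormIntensities(s, cfg)
  same <- corruptHolograms(h, NoiseModel(enabled = FALSE), mis = NULL)
  expect_identical(hologramImages(same), hologramImages(h))

  n1 <- corruptHolograms(h, NoiseModel(seed = 99))
  n2 <- corruptHolograms(h, NoiseModel(seed = 99))
  n3 <- corruptHolograms(h, NoiseModel(seed = 100))
  expect_identical(hologramImages(n1), hologramImages(n2))
  expect_gt(maxAbs(hologramImages(n1)$ccd1 -
    hologramImages(n3)$ccd1), 0)
  # quantization to the camera bit depth
  expect_true(all(hologramImages(n1)$ccd2 * (2^12 - 1) ==
    round(hologramImages(n1)$ccd2 * (2^12 - 1))))
})

test_that("read noise cannot improve phase recovery", {
  set.seed(31)
  s <- randomSmoothSample(c(48, 48), maxPhase = 2)
  cfg <- OpticalConfig(dims = c(48, 48))
  h <- closedFormIntensities(s, cfg)
  truthW <- wrapToPi(truthPhase(s))
  rmse <- function(sigma) {
    errs <- vapply(1:6, function(k) {
      hn <- corruptHolograms(h, NoiseModel(shotNoise = FALSE,
        readNoiseSigma = sigma, seed = 700 + k))
      w <- phaseValues(wrappedPhase(hn))
      sqrt(mean(wrapToPi(w - truthW)^2))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(rmse(2), rmse(20))
  expect_lt(rmse(20), rmse(80))
})
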
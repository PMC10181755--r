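test_that("chart generators keep phase and thickness consistent with the OPD relation", {
  tgt <- usafPhaseTarget(list(c(8, 1)), height = 0.2138,
    dims = c(256, 256), pixelSize = 0.345, wavelength = 0.532)
  k <- 2 * pi * (1.52 - 1.0) / 0.532
  expect_lt(maxAbs(truthPhase(tgt) - k * truthThickness(tgt)),
    1e-9 * max(truthPhase(tgt)))

  bead <- beadField(beadSpec(10), nMedium = 1.51, dims = c(128, 128),
    pixelSize = 0.345, wavelength = 0.532)
  kb <- 2 * pi * (1.49 - 1.51) / 0.532
  expect_lt(maxAbs(truthPhase(bead) - kb * truthThickness(bead)),
    1e-9 * maxAbs(truthPhase(bead)))
})

test_that("chart features carry the OPD phase of their etch height", {
  h <- 0.2138
  tgt <- usafPhaseTarget(list(c(8, 1)), height = h, dims = c(256, 256),
    pixelSize = 0.345, wavelength = 0.532)
  expected <- 2 * pi * 0.52 * h / 0.532
  # interior of the square pad sits exactly at the feature phase
  fr <- usafFeatureROI(tgt, 8, 1)
  inside <- truthPhase(tgt)[fr$row + seq_len(fr$nrow) - 1,
                            fr$col + seq_len(fr$ncol) - 1]
  expect_equal(max(inside), expected, tolerance = 1e-12)
  expect_equal(min(inside), expected, tolerance = 1e-12)
  # substrate is flat zero; zero height gives a blank field
  sr <- usafSubstrateROI(tgt, 8, 1)
  expect_equal(maxAbs(truthPhase(tgt)[sr$row + seq_len(sr$nrow) - 1,
    sr$col + seq_len(sr$ncol) - 1]), 0)
  blank <- usafPhaseTarget(list(c(8, 1)), height = 0,
    dims = c(256, 256), pixelSize = 0.345)
  expect_equal(maxAbs(truthPhase(blank)), 0)
})

test_that("anti-aliasing produces fractional edge coverage, binary mode does not", {
  aa <- usafPhaseTarget(list(c(7, 2)), height = 0.2, dims = c(256, 256),
    pixelSize = 0.345, antialias = TRUE)
  bin <- usafPhaseTarget(list(c(7, 2)), height = 0.2,
    dims = c(256, 256), pixelSize = 0.345, antialias = FALSE)
  tb <- truthThickness(bin)
  expect_true(all(tb %in% c(0, 0.2)))
  ta <- truthThickness(aa)
  expect_gt(sum(ta > 0 & ta < 0.2), 0)
  expect_error(
    usafPhaseTarget(list(c(2, 1)), dims = c(64, 64), pixelSize = 0.345),
    "does not fit")
})

test_that("bead profile peaks at the analytic apex phase and is radially symmetric", {
  px <- 0.345
  # centre the bead exactly on a pixel centre so the apex is sampled
  ctr <- c(64.5, 64.5) * px
  bead <- beadField(beadSpec(10, center = ctr), nMedium = 1.51,
    dims = c(129, 129), pixelSize = px, wavelength = 0.532)
  peak <- maxAbs(truthPhase(bead))
  expect_equal(peak, 2 * pi * 0.02 * 10 / 0.532, tolerance = 1e-12)
  # symmetric under both axis flips about the centred apex
  v <- truthPhase(bead)[1:129, 1:129]
  expect_lt(maxAbs(v - v[129:1, ]), 1e-12)
  expect_lt(maxAbs(v - v[, 129:1]), 1e-12)
})

test_that("index-matched and vanishing beads are invisible", {
  m <- beadField(beadSpec(10, nSample = 1.51), nMedium = 1.51,
    dims = c(64, 64), pixelSize = 0.345)
  expect_equal(maxAbs(truthPhase(m)), 0)
  tiny <- beadField(beadSpec(1e-6), nMedium = 1.51, dims = c(64, 64),
    pixelSize = 0.345)
  expect_lt(maxAbs(truthPhase(tiny)), 1e-6)
  expect_error(beadSpec(-1))
})

test_that("moving-bead frames follow the downward kinematics", {
  b <- beadSpec(6, center = c(10, 8))
  frames <- movingBeadSequence(b, velocity = 9, fps = 30, nFrames = 3,
    dims = c(96, 64), pixelSize = 0.345)
  expect_length(frames, 3)
  # displacement between consecutive frames is velocity / fps, along +y
  c0 <- sampleMeta(frames[[1]])$beads[[1]]$center
  c1 <- sampleMeta(frames[[2]])$beads[[1]]$center
  expect_equal(c1 - c0, c(0, 9 / 30))
  # the phase pattern itself shifts down: frame 2 at row r matches
  # frame 1 shifted by (velocity / fps) / pixelSize rows
  static <- movingBeadSequence(b, velocity = 0, fps = 30, nFrames = 3,
    dims = c(96, 64), pixelSize = 0.345)
  expect_equal(truthPhase(static[[1]]), truthPhase(static[[3]]))
  w <- capture_warnings(
    movingBeadSequence(beadSpec(6, center = c(10, 31)), velocity = 60,
      fps = 30, nFrames = 3, dims = c(96, 64), pixelSize = 0.345))
  expect_gt(length(w), 0)
  expect_match(w, "clipped", all = TRUE)
})

test_that("texture targets are pure-amplitude scenes within the requested range", {
  set.seed(3)
  tex <- textureTarget(c(64, 64), 0.345, range = c(0.3, 1))
  expect_equal(maxAbs(truthPhase(tex)), 0)
  a <- Mod(transmission(tex))
  expect_gte(min(a), 0.3 - 1e-12)
  expect_lte(max(a), 1 + 1e-12)
})
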
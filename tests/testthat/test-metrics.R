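test_that("USAF line widths follow the standard group/element geometry", {
  expect_equal(round(usafLinewidth(8, 4), 3), 1.381)
  expect_equal(usafLinewidth(5, 1), 500 / 2^5)
  expect_equal(usafLinewidth(7, 6) / usafLinewidth(8, 1), 2^(1 / 6))
  # elements within a group shrink by 2^(-1/6)
  for (e in 1:5)
    expect_equal(usafLinewidth(6, e + 1) / usafLinewidth(6, e),
      2^(-1 / 6))
})

test_that("three-bar resolvability detects square waves and rejects flat profiles", {
  sq <- rep(c(0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 0),
    each = 4)
  r <- resolvable(sq, smooth = 1)
  expect_true(r$resolvable)
  expect_equal(r$contrast, 1.0)
  flat <- rep(1, 50)
  r0 <- resolvable(flat)
  expect_false(r0$resolvable)
  expect_equal(r0$contrast, 0)
  # two bars only: not resolvable as a triplet
  two <- rep(c(0, 1, 0, 1, 0), each = 6)
  expect_false(resolvable(two, smooth = 1)$resolvable)
})

test_that("simulated charts resolve above the diffraction limit and not below", {
  px <- 0.345
  dims <- c(200, 200)
  cfg <- OpticalConfig(dims = dims, pupilEnabled = TRUE)
  gamma <- theoreticalResolution(0.532, 0.25)
  contrastOf <- function(g, e) {
    tgt <- usafPhaseTarget(list(c(g, e)), height = 0.35, dims = dims,
      pixelSize = px, margin = 12 * px)
    ph <- wrappedPhase(closedFormIntensities(tgt, cfg))
    w <- usafLinewidth(g, e)
    f <- sampleMeta(tgt)$features
    vb <- f[f$type == "vbar", ][1, ]
    rowpx <- (vb$y + 2.5 * w) / px
    resolvable(extractProfile(ph, from = c(rowpx, (vb$x - w) / px),
      to = c(rowpx, (vb$x + 6 * w) / px), n = 160))
  }
  r84 <- contrastOf(8, 4)   # 1.381 um > gamma: resolved
  expect_true(r84$resolvable)
  r93 <- contrastOf(9, 3)   # 0.776 um <= 0.8 * gamma: not resolved
  expect_false(r93$resolvable)
  # contrast is monotone in line width across the cutoff
  widths <- list(c(8, 1), c(8, 4), c(9, 1), c(9, 3))
  cs <- vapply(widths, function(ge)
    contrastOf(ge[1], ge[2])$contrast, numeric(1))
  seen <- cs >= 0.2
  expect_true(all(diff(as.integer(seen)) <= 0))
})

test_that("ROI step heights are exact on ground-truth maps and validate their inputs", {
  px <- 0.345
  tgt <- usafPhaseTarget(list(c(8, 1)), height = 0.2138,
    dims = c(256, 256), pixelSize = px)
  tm <- ThicknessMap(truthThickness(tgt), pixelSize = px)
  fr <- usafFeatureROI(tgt, 8, 1)
  sr <- usafSubstrateROI(tgt, 8, 1)
  expect_equal(stepHeight(tm, fr, sr), 0.2138, tolerance = 1e-12)
  expect_error(stepHeight(tm, fr, fr), "overlap")
  expect_error(stepHeight(tm, fr, roi(250, 250, 20, 20)), "bounds")
})

test_that("repeat statistics summarize estimates the way results are reported", {
  one <- repeatStats(3.7)
  expect_equal(one@mean, 3.7)
  expect_equal(one@sd, 0)
  expect_equal(one@n, 1L)
  const <- repeatStats(rep(2.5, 8))
  expect_equal(const@sd, 0)
  expect_error(repeatStats(numeric(0)), "no estimates")
  set.seed(33)
  est <- 0.2138 + rnorm(20, sd = 0.003)
  st <- repeatStats(est)
  expect_lt(abs(st@mean - 0.2138), 2 * st@sd / sqrt(20) + 3e-3)
  expect_equal(st@n, 20L)
})

test_that("bead peak phase reads the apex and is position invariant", {
  px <- 0.345
  analytic <- 2 * pi * 0.02 * 10 / 0.532
  peakAt <- function(center_px) {
    b <- beadField(beadSpec(10, center = center_px * px),
      nMedium = 1.51, dims = c(160, 160), pixelSize = px)
    pm <- PhaseMap(truthPhase(b), wrapped = FALSE, pixelSize = px)
    beadPeakPhase(pm, center = rev(center_px), smooth = 1)
  }
  p1 <- peakAt(c(80.5, 80.5))
  expect_equal(p1, analytic, tolerance = 2e-3)
  # off-centre and off-pixel-grid placements agree within 1%
  p2 <- peakAt(c(55.2, 97.8))
  expect_lt(abs(p2 - p1) / p1, 0.01)
  # flat field reads zero
  flat <- PhaseMap(matrix(0, 64, 64), wrapped = FALSE)
  expect_equal(beadPeakPhase(flat), 0)
})

test_that("profiles are sampled bilinearly between the requested endpoints", {
  m <- outer(1:10, 1:10, function(r, c) r + 10 * c)
  pr <- extractProfile(m, from = c(2, 3), to = c(2, 7), n = 5)
  expect_equal(pr$value, 2 + 10 * (3:7))
  expect_equal(nrow(pr), 5)
})
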
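#' @include AllClasses.R
NULL

phaseScale <- function(wavelength, nSample, nMedium)
  2 * pi * (nSample - nMedium) / wavelength

## Per-pixel coverage fraction of the interval [a, b] (um) by pixels of
## size p: pixel j covers [(j-1)p, jp).
cov1d <- function(n, p, a, b) {
  lo <- pmax((seq_len(n) - 1) * p, a)
  hi <- pmin(seq_len(n) * p, b)
  pmax(hi - lo, 0) / p
}

cov1dBinary <- function(n, p, a, b) {
  ctr <- (seq_len(n) - 0.5) * p
  as.numeric(ctr >= a & ctr < b)
}

#' Uniform (empty) sample field
#'
#' Unit transmission and zero phase everywhere; the calibration scene.
#'
#' @param dims grid size `c(rows, cols)`.
#' @param pixelSize um per pixel.
#' @param nMedium medium refractive index.
#' @return a [SampleField].
#' @export
emptyField <- function(dims = c(512L, 512L), pixelSize = 0.345,
    nMedium = 1.0) {
  z <- matrix(0, dims[1L], dims[2L])
  SampleField(transmission = z + (1 + 0i), pixelSize = pixelSize,
    truthPhase = z, truthThickness = z, nSample = nMedium,
    nMedium = nMedium, meta = list(type = "empty"))
}

#' Synthetic USAF 1951 phase target
#'
#' Generates a transparent phase-only resolution chart: for each
#' requested (group, element) a block of three vertical bars, three
#' horizontal bars and a square pad, all etched to a common height on a
#' flat substrate. Element (g, e) has the standard line width
#' `w = 500 / 2^(g + (e-1)/6)` um, bar length `5*w` and bar pitch `2*w`.
#' Feature pixels carry phase `(2*pi/lambda) * (n_s - n_m) * height`;
#' the substrate carries zero. The amplitude is 1 everywhere.
#'
#' Feature edges are anti-aliased by exact pixel-area coverage unless
#' `antialias = FALSE`, which rasterizes by pixel-centre membership.
#' The generated feature rectangles are recorded in
#' `sampleMeta(x)$features` (um units, top-left origin).
#'
#' @param elements list of `c(group, element)` pairs.
#' @param height etch height (um), > 0 (0 gives a blank substrate).
#' @param nSample,nMedium refractive indices (glass chart: 1.52 in air).
#' @param dims,pixelSize grid geometry.
#' @param wavelength um, used for the truth phase.
#' @param antialias pixel-area edge anti-aliasing flag.
#' @param margin top-left margin (um); default `8 * pixelSize`.
#' @return a [SampleField].
#' @examples
#' usafLinewidth(8, 4)  # 1.381 um
#' tgt <- usafPhaseTarget(list(c(7, 1)), height = 0.2138,
#'   dims = c(256, 256), pixelSize = 0.345)
#' @export
usafPhaseTarget <- function(elements = list(c(7, 1)), height = 0.2138,
    nSample = 1.52, nMedium = 1.0, dims = c(512L, 512L),
    pixelSize = 0.345, wavelength = 0.532, antialias = TRUE,
    margin = NULL) {
  stopifnot(height >= 0)
  nr <- as.integer(dims[1L]); nc <- as.integer(dims[2L])
  fw <- nc * pixelSize; fh <- nr * pixelSize
  if (is.null(margin)) margin <- 8 * pixelSize
  rects <- list()
  ycur <- margin
  for (ge in elements) {
    g <- ge[1L]; e <- ge[2L]
    w <- usafLinewidth(g, e)
    x0 <- margin
    ## vertical three-bar triplet (bars w wide, 5w tall, pitch 2w)
    for (k in 0:2)
      rects[[length(rects) + 1L]] <- list(group = g, element = e,
        type = "vbar", x = x0 + 2 * k * w, y = ycur, w = w, h = 5 * w)
    ## horizontal triplet
    xh <- x0 + 5 * w + 2 * w
    for (k in 0:2)
      rects[[length(rects) + 1L]] <- list(group = g, element = e,
        type = "hbar", x = xh, y = ycur + 2 * k * w, w = 5 * w, h = w)
    ## square pad
    xs <- xh + 5 * w + 2 * w
    rects[[length(rects) + 1L]] <- list(group = g, element = e,
      type = "square", x = xs, y = ycur, w = 5 * w, h = 5 * w)
    if (xs + 5 * w > fw - margin / 2 || ycur + 5 * w > fh - margin / 2)
      stop(sprintf(
        "USAF element (%d, %d) does not fit on the %.1f x %.1f um grid",
        g, e, fw, fh), call. = FALSE)
    ycur <- ycur + 5 * w + 2 * w
  }
  covfun <- if (antialias) cov1d else cov1dBinary
  coverage <- matrix(0, nr, nc)
  for (r in rects) {
    cx <- covfun(nc, pixelSize, r$x, r$x + r$w)
    cy <- covfun(nr, pixelSize, r$y, r$y + r$h)
    jj <- which(cx > 0); ii <- which(cy > 0)
    if (length(ii) && length(jj))
      coverage[ii, jj] <- pmin(coverage[ii, jj, drop = FALSE] +
        outer(cy[ii], cx[jj]), 1)
  }
  thick <- coverage * height
  phase <- phaseScale(wavelength, nSample, nMedium) * thick
  feats <- do.call(rbind, lapply(rects, as.data.frame))
  SampleField(transmission = exp(1i * phase), pixelSize = pixelSize,
    truthPhase = phase, truthThickness = thick, nSample = nSample,
    nMedium = nMedium,
    meta = list(type = "usaf", height = height, features = feats,
      wavelength = wavelength))
}

#' Feature and substrate ROIs of a generated chart
#'
#' Convenience lookups into the feature table of [usafPhaseTarget()]:
#' `usafFeatureROI` returns the inner fraction of the square pad of an
#' element; `usafSubstrateROI` returns an equally sized patch of bare
#' substrate immediately to the right of that pad.
#'
#' @param sample a [SampleField] produced by [usafPhaseTarget()].
#' @param group,element chart element.
#' @param inner linear fraction of the pad retained (default 0.6).
#' @return an [roi()].
#' @export
usafFeatureROI <- function(sample, group, element, inner = 0.6) {
  sq <- .usafSquare(sample, group, element)
  p <- pixelSize(sample)
  side <- sq$w * inner
  x0 <- sq$x + (sq$w - side) / 2
  y0 <- sq$y + (sq$h - side) / 2
  roi(row = floor(y0 / p) + 1L, col = floor(x0 / p) + 1L,
    nrow = max(1L, floor(side / p)), ncol = max(1L, floor(side / p)))
}

#' @rdname usafFeatureROI
#' @export
usafSubstrateROI <- function(sample, group, element, inner = 0.6) {
  sq <- .usafSquare(sample, group, element)
  p <- pixelSize(sample)
  side <- sq$w * inner
  x0 <- sq$x + sq$w + 2 * usafLinewidth(group, element) +
    (sq$w - side) / 2
  y0 <- sq$y + (sq$h - side) / 2
  r <- roi(row = floor(y0 / p) + 1L, col = floor(x0 / p) + 1L,
    nrow = max(1L, floor(side / p)), ncol = max(1L, floor(side / p)))
  d <- dim(truthPhase(sample))
  if (r$col + r$ncol - 1L > d[2L])
    stop("no room for a substrate ROI right of the square pad")
  r
}

.usafSquare <- function(sample, group, element) {
  f <- sampleMeta(sample)$features
  sel <- f$type == "square" & f$group == group & f$element == element
  if (!any(sel)) stop("element not present in this target")
  as.list(f[which(sel)[1L], ])
}

#' Spherical bead sample field
#'
#' Pure-phase field of transparent spheres: the projected thickness of a
#' bead of diameter `d` at in-plane distance `rho` from its centre is
#' `2 * sqrt((d/2)^2 - rho^2)` (0 outside), and the phase is
#' `(2*pi/lambda) * (n_s - n_m) * thickness` per bead; overlapping beads
#' add. Beads denser in index than the medium give positive phase,
#' beads in higher-index oil (e.g. PMMA at 1.49 in 1.51 oil) negative.
#'
#' @param beads a [beadSpec()] or list of them.
#' @param nMedium medium refractive index.
#' @param dims,pixelSize grid geometry.
#' @param wavelength um.
#' @return a [SampleField]; `truthThickness` holds the summed projected
#'   thickness, `nSample` the bead index (NA if beads differ).
#' @examples
#' b <- beadField(beadSpec(10), nMedium = 1.51, dims = c(128, 128))
#' max(abs(truthPhase(b)))  # ~ 2.362 rad for a 10 um bead, |dn| = 0.02
#' @export
beadField <- function(beads, nMedium = 1.51, dims = c(512L, 512L),
    pixelSize = 0.345, wavelength = 0.532) {
  if (inherits(beads, "beadSpec")) beads <- list(beads)
  nr <- as.integer(dims[1L]); nc <- as.integer(dims[2L])
  xs <- (seq_len(nc) - 0.5) * pixelSize
  ys <- (seq_len(nr) - 0.5) * pixelSize
  thick <- matrix(0, nr, nc)
  phase <- matrix(0, nr, nc)
  ns <- vapply(beads, function(b) b$nSample, numeric(1))
  for (b in beads) {
    ctr <- if (is.null(b$center))
      c(nc, nr) / 2 * pixelSize else b$center
    r2 <- (b$diameter / 2)^2 -
      outer((ys - ctr[2L])^2, (xs - ctr[1L])^2, "+")
    tb <- 2 * sqrt(pmax(r2, 0))
    thick <- thick + tb
    phase <- phase + phaseScale(wavelength, b$nSample, nMedium) * tb
  }
  SampleField(transmission = exp(1i * phase), pixelSize = pixelSize,
    truthPhase = phase, truthThickness = thick,
    nSample = if (length(unique(ns)) == 1L) ns[1L] else NA_real_,
    nMedium = nMedium,
    meta = list(type = "beads", beads = beads, wavelength = wavelength))
}

#' Sinking-bead frame sequence
#'
#' Frames of a single bead translating along +y (downward) at constant
#' velocity, as for a pellet sinking under gravity; frame `k` (0-based)
#' has the centre displaced by `velocity * k / fps`.
#'
#' @param bead a [beadSpec()]; `NULL` centre starts at the grid centre.
#' @param velocity um per second.
#' @param fps frame rate (frames per second).
#' @param nFrames number of frames (>= 1).
#' @inheritParams beadField
#' @return list of [SampleField] frames. A warning is issued for frames
#'   in which the bead is clipped by the grid boundary (the frame is
#'   still produced).
#' @export
movingBeadSequence <- function(bead, velocity, fps = 30, nFrames = 7,
    nMedium = 1.51, dims = c(512L, 512L), pixelSize = 0.345,
    wavelength = 0.532) {
  stopifnot(nFrames >= 1)
  ctr0 <- if (is.null(bead$center))
    c(dims[2L], dims[1L]) / 2 * pixelSize else bead$center
  r <- bead$diameter / 2
  lapply(seq_len(nFrames) - 1L, function(k) {
    ctr <- ctr0 + c(0, velocity * k / fps)
    if (ctr[2L] + r > dims[1L] * pixelSize || ctr[2L] - r < 0)
      warning(sprintf("frame %d: bead clipped by the grid boundary", k),
        call. = FALSE)
    b <- bead; b$center <- ctr
    beadField(b, nMedium = nMedium, dims = dims, pixelSize = pixelSize,
      wavelength = wavelength)
  })
}

#' Amplitude-textured registration target
#'
#' A zero-phase scene with smooth pseudo-random amplitude texture. All
#' four channels image the texture with the same (monotone) contrast
#' relation, which makes it the scene of choice for the one-time channel
#' registration; phase samples in exact quadrature would instead give
#' channels with inverted fringe contrast.
#'
#' @param dims,pixelSize grid geometry.
#' @param range amplitude range `c(lo, hi)` within (0, 1].
#' @param corLen texture correlation length (px).
#' @param nMedium medium index (for the truth bookkeeping only).
#' @return a [SampleField] with zero truth phase.
#' @export
textureTarget <- function(dims = c(512L, 512L), pixelSize = 0.345,
    range = c(0.3, 1), corLen = 6, nMedium = 1.0) {
  a <- range[1L] + (range[2L] - range[1L]) *
    smoothRandomField(dims, corLen)
  z <- matrix(0, dims[1L], dims[2L])
  SampleField(transmission = a + 0i, pixelSize = pixelSize,
    truthPhase = z, truthThickness = z, nSample = nMedium,
    nMedium = nMedium, meta = list(type = "texture"))
}
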
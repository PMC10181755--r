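#' @include AllClasses.R jones.R samples.R
NULL

#' Object-plane pixel size
#'
#' Camera pixel pitch divided by the lateral magnification.
#'
#' @param cfg an [OpticalConfig].
#' @return um per object-plane pixel (default hardware:
#'   3.45 um / 10x = 0.345 um).
#' @export
objectPixelSize <- function(cfg) cfg@pixelPitch / cfg@magnification

.checkSampleCfg <- function(sample, cfg) {
  if (!identical(dim(transmission(sample)), as.integer(cfg@dims)))
    stop("sample grid does not match the configured image dims",
      call. = FALSE)
}

## Coherent pupil low-pass of a complex field: circular cutoff of radius
## NA/lambda in spatial frequency.
pupilFilter <- function(field, pixelSize, na, wavelength) {
  nr <- nrow(field); nc <- ncol(field)
  fy <- fftFreq(nr, pixelSize); fx <- fftFreq(nc, pixelSize)
  mask <- outer(fy^2, fx^2, "+") <= (na / wavelength)^2
  fft(fft(field) * mask, inverse = TRUE) / (nr * nc)
}

#' Coherent pupil filtering of a sample field
#'
#' Low-pass filters the complex transmission with the circular coherent
#' transfer function of radius `NA / lambda`; spatial structure finer
#' than the diffraction limit is removed before interference. Energy is
#' non-increasing. The ground-truth maps are left untouched.
#'
#' @param sample a [SampleField].
#' @param cfg an [OpticalConfig] (its `na` and `wavelength` are used).
#' @return a [SampleField] with band-limited transmission.
#' @export
applyPupil <- function(sample, cfg) {
  t2 <- pupilFilter(transmission(sample), pixelSize(sample), cfg@na,
    cfg@wavelength)
  ## filtering ringing can overshoot |t| = 1 slightly; clamp amplitude
  a <- Mod(t2)
  over <- a > 1
  if (any(over)) t2[over] <- t2[over] / a[over]
  initialize(sample, transmission = t2)
}

.interferenceTerms <- function(sample, cfg) {
  tr <- transmission(sample)
  if (cfg@pupilEnabled)
    tr <- transmission(applyPupil(sample, cfg))
  u <- tr * exp(1i * cfg@armPhaseOffset)
  list(alpha = Mod(tr), u = u)
}

#' Closed-form four-channel hologram intensities
#'
#' Direct evaluation of the system's closed-form output: with
#' `dphi = phi_sample + armPhaseOffset`,
#' \deqn{I_{1,2} = \tfrac14[\alpha^2 A_O^2 + A_R^2 \pm
#'   2\alpha A_O A_R \cos\Delta\varphi]}
#' \deqn{I_{3,4} = \tfrac14[\alpha^2 A_O^2 + A_R^2 \pm
#'   2\alpha A_O A_R \sin\Delta\varphi]}
#' Noise-free and perfectly aligned.
#'
#' @param sample a [SampleField] whose grid matches `cfg@dims`.
#' @param cfg an [OpticalConfig].
#' @return a [HologramSet]; the common DC level is stored in its
#'   `background` slot.
#' @export
closedFormIntensities <- function(sample, cfg = OpticalConfig(
    dims = dim(transmission(sample)))) {
  .checkSampleCfg(sample, cfg)
  it <- .interferenceTerms(sample, cfg)
  ao <- cfg@amplitudeObject; ar <- cfg@amplitudeReference
  dc <- 0.25 * (it$alpha^2 * ao^2 + ar^2)
  cc <- 0.5 * ao * ar * Re(it$u)
  ss <- 0.5 * ao * ar * Im(it$u)
  HologramSet(
    images = list(ccd1 = dc + cc, ccd2 = dc - cc,
                  ccd3 = dc + ss, ccd4 = dc - ss),
    pixelSize = pixelSize(sample), background = dc)
}

#' Jones-chain propagation through the four-channel interferometer
#'
#' Explicitly propagates object and reference waves through the element
#' chain: 45-degree polarizer and quarter-wave plate on both arms (the
#' object-arm plate is aligned with the polarization and leaves the
#' state unchanged; the common unimodular amplitude factor it
#' contributes is dropped, consistent with the model's neglect of energy
#' loss), recombination and splitting at the first polarizing
#' beamsplitter (with half-wave loss on reflection), a 45-degree
#' quarter-wave plate on each output, and the final polarizing
#' beamsplitter routing the quadrature components to the four cameras.
#'
#' The result is identical (to machine precision) to
#' [closedFormIntensities()], which serves as its algebraic oracle.
#'
#' @inheritParams closedFormIntensities
#' @return a [HologramSet].
#' @export
propagateSystem <- function(sample, cfg = OpticalConfig(
    dims = dim(transmission(sample)))) {
  .checkSampleCfg(sample, cfg)
  tr <- transmission(sample)
  if (cfg@pupilEnabled) tr <- transmission(applyPupil(sample, cfg))
  ao <- cfg@amplitudeObject; ar <- cfg@amplitudeReference
  zero <- matrix(0, nrow(tr), ncol(tr))

  ## input fields: object wave carries the sample transmission and the
  ## inter-arm phase offset
  eo <- jonesVector(ao * tr * exp(1i * cfg@armPhaseOffset), zero)
  er <- jonesVector(ar * (1 + zero), zero)

  p45 <- elementMatrix("polarizer45")
  eoP <- jonesApply(p45, eo)
  erP <- jonesApply(p45, er)

  ## object arm: QWP with fast axis at 45 deg, aligned with the
  ## polarization; (1,1) is an eigenvector with eigenvalue (1 - i),
  ## which is dropped (energy loss and global phase are ignored)
  eoQ <- jonesApply(elementMatrix("qwp45_fast"), eoP) / (1 - 1i)
  ## reference arm: QWP fast axis along x -> circular polarization
  erQ <- jonesApply(elementMatrix("qwp_x"), erP)

  ## first PBS: amplitude split (1/2 prefactor), half-wave loss on
  ## reflection
  tm <- elementMatrix("pbs_transmit")
  rm <- elementMatrix("pbs_reflect")
  m0 <- jonesApply(tm, eoQ) + jonesApply(rm, erQ)
  m1 <- jonesApply(rm, eoQ) + jonesApply(tm, erQ)

  q45s <- elementMatrix("qwp45_slow")
  m0q <- jonesApply(q45s, m0)
  m1q <- jonesApply(q45s, m1)

  ## final PBS only routes the already-separated quadratures
  tb <- elementMatrix("pbs_transmit", prefactor = "unit")
  rb <- elementMatrix("pbs_reflect", prefactor = "unit")
  HologramSet(
    images = list(
      ccd1 = intensity(jonesApply(tb, m0q)),
      ccd2 = intensity(jonesApply(rb, m0q)),
      ccd3 = intensity(jonesApply(tb, m1q)),
      ccd4 = intensity(jonesApply(rb, m1q))),
    pixelSize = pixelSize(sample))
}

#' Camera corruption: misalignment, noise and quantization
#'
#' Applies, in order: the per-channel geometric misalignment of cameras
#' 2-4 (affine resampling with bilinear interpolation, replicate
#' padding), Poisson shot noise on the expected photon counts, additive
#' Gaussian read noise, and quantization to the camera bit depth with
#' clipping at full scale (unit optical intensity). With noise disabled
#' and identity transforms the input is returned unchanged. Output is
#' deterministic for a fixed `noise@seed`.
#'
#' @param holos a [HologramSet].
#' @param noise a [NoiseModel] (disabled model: geometric warp only).
#' @param mis a [MisalignmentModel] or NULL.
#' @param bitDepth camera quantization depth (bits).
#' @return the corrupted [HologramSet].
#' @export
corruptHolograms <- function(holos, noise = NoiseModel(enabled = FALSE),
    mis = NULL, bitDepth = 12L) {
  if (is.null(mis) && !noise@enabled) return(holos)
  imgs <- hologramImages(holos)
  if (!is.null(mis)) {
    stopifnot(is(mis, "MisalignmentModel"))
    for (ch in names(mis@transforms)) {
      p <- mis@transforms[[ch]]
      tr <- paramsToAffine(p$tx, p$ty, p$rot, p$scale)
      imgs[[ch]] <- warpImage(imgs[[ch]], tr$A, tr$b)
    }
  }
  if (noise@enabled) {
    if (!is.na(noise@seed)) set.seed(as.integer(noise@seed))
    full <- 2^bitDepth - 1
    imgs <- lapply(imgs, function(im) {
      counts <- pmax(im, 0) * noise@photonScale
      if (noise@shotNoise)
        counts <- rpois(length(counts), counts)
      if (noise@readNoiseSigma > 0)
        counts <- counts + rnorm(length(counts),
          sd = noise@readNoiseSigma)
      dn <- round(counts / noise@photonScale * full)
      matrix(pmin(pmax(dn, 0), full) / full, nrow(im), ncol(im))
    })
  }
  initialize(holos, images = imgs, background = NULL)
}
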
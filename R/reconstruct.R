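#' @include AllClasses.R unwrap.R register.R
NULL

#' Four-step arctangent phase retrieval
#'
#' Recovers the wrapped object-reference phase difference from the four
#' registered holograms by the four-quadrant arctangent
#' `dphi = atan2(I_ccd3 - I_ccd4, I_ccd1 - I_ccd2)`, which cancels the
#' common DC level and recovers the full 2*pi range. Pixels where both
#' intensity differences fall below 1e-3 of the maximum fringe
#' modulation carry no usable fringe signal; their phase is set to 0 and
#' they are flagged FALSE in the validity mask.
#'
#' @param holos a [HologramSet] in pixelwise correspondence (see
#'   [applyRegistration()]).
#' @param modulationFloor relative threshold defining the validity mask.
#' @return a wrapped [PhaseMap].
#' @examples
#' one <- matrix(1, 8, 8); half <- matrix(0.5, 8, 8)
#' h <- HologramSet(list(ccd1 = half, ccd2 = half, ccd3 = one,
#'   ccd4 = 0 * one))
#' phaseValues(wrappedPhase(h))[1, 1]  # pi / 2
#' @export
wrappedPhase <- function(holos, modulationFloor = 1e-3) {
  imgs <- hologramImages(holos)
  num <- imgs$ccd3 - imgs$ccd4
  den <- imgs$ccd1 - imgs$ccd2
  phi <- atan2(num, den)
  phi[phi <= -pi] <- pi
  modMax <- max(sqrt(num^2 + den^2))
  valid <- !(abs(num) < modulationFloor * modMax &
             abs(den) < modulationFloor * modMax)
  phi[!valid] <- 0
  PhaseMap(values = phi, wrapped = TRUE, pixelSize = pixelSize(holos),
    validity = valid)
}

#' Calibration (empty-field) phase subtraction
#'
#' Subtracts the system's calibration phase, recorded without a sample,
#' from a wrapped measurement: removes the instrument's phase
#' aberration and the global object/reference arm offset. The result is
#' re-wrapped into `(-pi, pi]`.
#'
#' @param phase,calib wrapped [PhaseMap]s of identical dims.
#' @return a wrapped [PhaseMap]; validity masks are intersected.
#' @export
subtractCalibration <- function(phase, calib) {
  stopifnot(is(phase, "PhaseMap"), is(calib, "PhaseMap"),
    isWrapped(phase), isWrapped(calib))
  if (!identical(dim(phaseValues(phase)), dim(phaseValues(calib))))
    stop("phase and calibration maps must share dims", call. = FALSE)
  v <- wrapToPi(phaseValues(phase) - phaseValues(calib))
  mask <- validityMask(phase)
  if (!is.null(validityMask(calib)))
    mask <- if (is.null(mask)) validityMask(calib)
      else mask & validityMask(calib)
  PhaseMap(values = v, wrapped = TRUE, pixelSize = pixelSize(phase),
    validity = mask)
}

#' Phase-to-thickness conversion
#'
#' `dh = lambda * dphi / (2 * pi * (n_s - n_m))`. For maps the signed
#' formula is used; because the phase sign follows the sign of the index
#' contrast, physical samples on either side of the medium index come
#' out with non-negative heights (a bead in higher-index oil has
#' negative phase *and* negative contrast) while zero-mean noise stays
#' zero-mean. Numeric input is treated as a reported phase height
#' (a magnitude), so the conversion uses `|n_s - n_m|`.
#'
#' @param phase an unwrapped [PhaseMap], or a numeric vector of phase
#'   heights (rad) for scalar use.
#' @param wavelength um.
#' @param nSample,nMedium refractive indices; equal indices are an
#'   error (the optical path difference vanishes).
#' @return a [ThicknessMap] (um), or numeric for numeric input.
#' @examples
#' phaseToThickness(2.35, 0.532, 1.49, 1.51)  # 9.95 um
#' @export
phaseToThickness <- function(phase, wavelength = 0.532, nSample,
    nMedium) {
  if (nSample == nMedium)
    stop("nSample == nMedium: thickness is undefined", call. = FALSE)
  k <- wavelength / (2 * pi * (nSample - nMedium))
  if (is.numeric(phase)) return(abs(k) * phase)
  stopifnot(is(phase, "PhaseMap"))
  if (isWrapped(phase))
    warning("converting a wrapped phase map to thickness", call. = FALSE)
  ThicknessMap(values = k * phaseValues(phase),
    pixelSize = pixelSize(phase), wavelength = wavelength,
    nSample = nSample, nMedium = nMedium)
}

#' Theoretical lateral resolution
#'
#' Coherent two-point resolution `gamma = lambda / (2 * NA)`.
#'
#' @param wavelength um.
#' @param na numerical aperture (> 0).
#' @return resolution in um.
#' @examples
#' theoreticalResolution(0.532, 0.25)  # 1.064 um
#' @export
theoreticalResolution <- function(wavelength, na) {
  stopifnot(na > 0)
  wavelength / (2 * na)
}

#' Full reconstruction pipeline on in-memory hologram sets
#'
#' Chains the reconstruction workflow: (optional) application of cached
#' registration transforms to the sample and calibration sets, wrapped
#' phase retrieval, calibration subtraction, minimum-norm unwrapping and
#' thickness conversion.
#'
#' @param holos sample [HologramSet].
#' @param calib optional calibration [HologramSet] (recorded without a
#'   sample under the identical configuration); when missing,
#'   compensation is skipped with a warning.
#' @param registration optional [RegistrationResult] to apply to both
#'   sets.
#' @param wavelength,nSample,nMedium conversion constants.
#' @return list with elements `wrapped`, `compensated`, `unwrapped`
#'   ([PhaseMap]s) and `thickness` ([ThicknessMap]).
#' @export
reconstructHolograms <- function(holos, calib = NULL,
    registration = NULL, wavelength = 0.532, nSample, nMedium) {
  if (!is.null(registration)) {
    holos <- applyRegistration(holos, registration)
    if (!is.null(calib)) calib <- applyRegistration(calib, registration)
  }
  wrapped <- wrappedPhase(holos)
  compensated <- if (is.null(calib)) {
    warning("no calibration set supplied; compensation skipped",
      call. = FALSE)
    wrapped
  } else {
    subtractCalibration(wrapped, wrappedPhase(calib))
  }
  unwrapped <- unwrapPhase(compensated)
  thickness <- phaseToThickness(unwrapped, wavelength = wavelength,
    nSample = nSample, nMedium = nMedium)
  list(wrapped = wrapped, compensated = compensated,
    unwrapped = unwrapped, thickness = thickness)
}
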
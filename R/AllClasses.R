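#' @import methods
#' @importFrom stats cor optim rnorm rpois runif sd lm coef setNames
NULL

.CHANNELS <- c("ccd1", "ccd2", "ccd3", "ccd4")

## Nominal phase shift carried by each camera channel: the two outputs of the
## first polarizing beamsplitter are in antiphase (0 vs pi) and the second
## pair is in quadrature (pi/2 vs 3pi/2).
.PHASE_SHIFTS <- c(ccd1 = 0, ccd2 = pi, ccd3 = pi / 2, ccd4 = 3 * pi / 2)

#' Jones vector
#'
#' Two-component complex representation of a fully polarized field. The
#' basis is fixed: `ex` lies along the p-polarization direction (x), `ey`
#' along the s-polarization direction (y). Components may be complex
#' scalars or equally sized complex matrices (a field sampled on a pixel
#' grid), so a whole image propagates through the optical chain in one
#' object.
#'
#' @slot ex complex amplitude(s) along x.
#' @slot ey complex amplitude(s) along y.
#' @exportClass JonesVector
setClass("JonesVector", representation(ex = "ANY", ey = "ANY"),
  validity = function(object) {
    if (!is.complex(object@ex) && !is.numeric(object@ex))
      return("'ex' must be numeric or complex")
    if (!is.complex(object@ey) && !is.numeric(object@ey))
      return("'ey' must be numeric or complex")
    if (!identical(dim(object@ex), dim(object@ey)) ||
        length(object@ex) != length(object@ey))
      return("'ex' and 'ey' must have identical dimensions")
    TRUE
  })

#' @param ex,ey complex amplitudes (scalars or matrices of equal size).
#' @rdname JonesVector-class
#' @export
jonesVector <- function(ex, ey) {
  if (length(ex) == 1 && length(ey) > 1) ex <- ex + 0 * ey
  if (length(ey) == 1 && length(ex) > 1) ey <- ey + 0 * ex
  asC <- function(x) {
    d <- dim(x)
    x <- as.complex(x)
    dim(x) <- d
    x
  }
  new("JonesVector", ex = asC(ex), ey = asC(ey))
}

#' Jones matrix
#'
#' A 2x2 complex operator acting on [JonesVector] fields, labelled by the
#' optical element it represents.
#'
#' @slot m 2x2 complex matrix.
#' @slot label element kind (e.g. `"polarizer45"`, `"qwp_x"`).
#' @exportClass JonesMatrix
setClass("JonesMatrix", representation(m = "matrix", label = "character"),
  validity = function(object) {
    if (!all(dim(object@m) == c(2L, 2L))) return("'m' must be 2x2")
    TRUE
  })

#' Optical system configuration
#'
#' Physical parameters of the interferometer and imaging arm. Lengths are
#' in micrometres throughout the package.
#'
#' @slot wavelength laser wavelength (um).
#' @slot amplitudeObject,amplitudeReference wave amplitudes A_O, A_R.
#' @slot na numerical aperture of the microscope objective.
#' @slot magnification lateral magnification of the imaging system.
#' @slot pixelPitch camera pixel pitch (um); the object-plane sampling is
#'   `pixelPitch / magnification`.
#' @slot dims image size in pixels, `c(rows, cols)`.
#' @slot bitDepth camera quantization depth (bits).
#' @slot armPhaseOffset global phase offset between object and reference
#'   arms (rad); removed downstream by calibration subtraction.
#' @slot pupilEnabled apply the coherent NA/lambda pupil low-pass to the
#'   sample field before interference.
#' @exportClass OpticalConfig
setClass("OpticalConfig",
  representation(wavelength = "numeric", amplitudeObject = "numeric",
    amplitudeReference = "numeric", na = "numeric",
    magnification = "numeric", pixelPitch = "numeric", dims = "integer",
    bitDepth = "integer", armPhaseOffset = "numeric",
    pupilEnabled = "logical"),
  validity = function(object) {
    if (object@wavelength <= 0) return("wavelength must be > 0")
    if (object@na <= 0 || object@na > 1) return("na must be in (0, 1]")
    if (object@amplitudeObject < 0 || object@amplitudeReference < 0)
      return("amplitudes must be >= 0")
    if (length(object@dims) != 2L || any(object@dims < 1L))
      return("dims must be two positive integers")
    if (object@pixelPitch <= 0 || object@magnification <= 0)
      return("pixelPitch and magnification must be > 0")
    TRUE
  })

#' @param wavelength,amplitudeObject,amplitudeReference,na,magnification
#'   see slots.
#' @param pixelPitch,dims,bitDepth,armPhaseOffset,pupilEnabled see slots.
#' @rdname OpticalConfig-class
#' @export
OpticalConfig <- function(wavelength = 0.532, amplitudeObject = 1,
    amplitudeReference = 1, na = 0.25, magnification = 10,
    pixelPitch = 3.45, dims = c(512L, 512L), bitDepth = 12L,
    armPhaseOffset = 0, pupilEnabled = FALSE) {
  new("OpticalConfig", wavelength = wavelength,
    amplitudeObject = amplitudeObject,
    amplitudeReference = amplitudeReference, na = na,
    magnification = magnification, pixelPitch = pixelPitch,
    dims = as.integer(dims), bitDepth = as.integer(bitDepth),
    armPhaseOffset = armPhaseOffset, pupilEnabled = pupilEnabled)
}

#' Camera noise model
#'
#' Poisson shot noise on expected photon counts, additive Gaussian read
#' noise, and quantization to the camera bit depth.
#'
#' @slot enabled master switch; when `FALSE` images pass unchanged.
#' @slot shotNoise Poisson-sample the expected counts.
#' @slot readNoiseSigma read noise standard deviation (counts).
#' @slot photonScale expected counts at unit optical intensity; unit
#'   intensity maps to the camera full scale.
#' @slot seed RNG seed (NA: leave the RNG state alone).
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(enabled = "logical", shotNoise = "logical",
    readNoiseSigma = "numeric", photonScale = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@readNoiseSigma < 0) return("readNoiseSigma must be >= 0")
    if (object@photonScale <= 0) return("photonScale must be > 0")
    TRUE
  })

#' @param enabled,shotNoise,readNoiseSigma,photonScale,seed see slots.
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(enabled = TRUE, shotNoise = TRUE,
    readNoiseSigma = 3, photonScale = 2000, seed = NA_real_) {
  new("NoiseModel", enabled = enabled, shotNoise = shotNoise,
    readNoiseSigma = readNoiseSigma, photonScale = photonScale,
    seed = seed)
}

#' Per-channel geometric misalignment
#'
#' Affine misalignment of cameras 2-4 relative to camera 1, parameterized
#' as translation (px), rotation (degrees, about the image centre) and
#' isotropic scale. Camera 1 is the reference and is never transformed.
#'
#' @slot transforms named list (`ccd2`..`ccd4`) of lists with elements
#'   `tx`, `ty`, `rot`, `scale`.
#' @exportClass MisalignmentModel
setClass("MisalignmentModel", representation(transforms = "list"),
  validity = function(object) {
    nm <- names(object@transforms)
    if (!all(nm %in% .CHANNELS[-1]))
      return("transform names must be among ccd2, ccd3, ccd4")
    for (tr in object@transforms) {
      if (!all(c("tx", "ty", "rot", "scale") %in% names(tr)))
        return("each transform needs tx, ty, rot, scale")
      if (tr$scale == 0) return("scale must be non-zero (invertible)")
    }
    TRUE
  })

#' @param ccd2,ccd3,ccd4 lists with `tx`, `ty` (px), `rot` (deg),
#'   `scale`; `NULL` means identity for that channel.
#' @rdname MisalignmentModel-class
#' @export
MisalignmentModel <- function(ccd2 = NULL, ccd3 = NULL, ccd4 = NULL) {
  fill <- function(x) {
    if (is.null(x)) return(NULL)
    utils::modifyList(list(tx = 0, ty = 0, rot = 0, scale = 1), x)
  }
  tr <- Filter(Negate(is.null),
    list(ccd2 = fill(ccd2), ccd3 = fill(ccd3), ccd4 = fill(ccd4)))
  new("MisalignmentModel", transforms = tr)
}

#' Synthetic sample field
#'
#' Complex transmission `alpha(x,y) * exp(i*phi(x,y))` of a transparent
#' object on a pixel grid, carrying its ground-truth phase (rad) and
#' thickness (um) maps. The truth phase always satisfies
#' `phi = (2*pi/lambda) * (n_s - n_m) * thickness` pointwise.
#'
#' @slot transmission complex matrix.
#' @slot pixelSize object-plane pixel size (um).
#' @slot truthPhase,truthThickness real matrices (rad / um).
#' @slot nSample,nMedium refractive indices (nSample may be NA for
#'   mixed-index scenes).
#' @slot meta free-form list (feature tables, generator parameters).
#' @exportClass SampleField
setClass("SampleField",
  representation(transmission = "matrix", pixelSize = "numeric",
    truthPhase = "matrix", truthThickness = "matrix",
    nSample = "numeric", nMedium = "numeric", meta = "list"),
  validity = function(object) {
    d <- dim(object@transmission)
    if (!identical(dim(object@truthPhase), d) ||
        !identical(dim(object@truthThickness), d))
      return("truth maps must match transmission dims")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    a <- Mod(object@transmission)
    if (max(a) > 1 + 1e-9) return("transmission amplitude must be <= 1")
    TRUE
  })

#' @param transmission,pixelSize,truthPhase,truthThickness see slots.
#' @param nSample,nMedium,meta see slots.
#' @rdname SampleField-class
#' @export
SampleField <- function(transmission, pixelSize, truthPhase,
    truthThickness, nSample, nMedium, meta = list()) {
  new("SampleField", transmission = transmission, pixelSize = pixelSize,
    truthPhase = truthPhase, truthThickness = truthThickness,
    nSample = nSample, nMedium = nMedium, meta = meta)
}

#' Bead specification
#'
#' A spherical microsphere sample (e.g. a PMMA pellet) described by its
#' diameter (um), centre position on the grid (um, x = column direction,
#' y = row direction, origin at the top-left pixel centre) and refractive
#' index.
#'
#' @param diameter bead diameter (um), > 0.
#' @param center numeric length 2, `c(x, y)` in um; `NULL` = grid centre.
#' @param nSample bead refractive index (PMMA: 1.49).
#' @return a `beadSpec` list.
#' @export
beadSpec <- function(diameter = 10, center = NULL, nSample = 1.49) {
  stopifnot(diameter > 0)
  structure(list(diameter = diameter, center = center, nSample = nSample),
    class = "beadSpec")
}

#' Four-channel hologram set
#'
#' The four simultaneously recorded phase-shifted holograms. Channel
#' `ccd1` carries nominal shift 0, `ccd3` pi/2, `ccd2` pi and `ccd4`
#' 3*pi/2. Noise-free, aligned sets satisfy the channel-sum conservation
#' `I1 + I2 = I3 + I4` pointwise.
#'
#' @slot images named list of four real matrices (`ccd1`..`ccd4`).
#' @slot phaseShifts named numeric, the delta_i of each channel.
#' @slot pixelSize object-plane pixel size (um).
#' @slot background optional DC level I0(x,y) (matrix or NULL).
#' @exportClass HologramSet
setClass("HologramSet",
  representation(images = "list", phaseShifts = "numeric",
    pixelSize = "numeric", background = "ANY"),
  validity = function(object) {
    if (!identical(sort(names(object@images)), sort(.CHANNELS)))
      return("images must be named ccd1..ccd4")
    d <- dim(object@images[[1L]])
    for (im in object@images)
      if (!identical(dim(im), d)) return("all channels must share dims")
    if (!all(.CHANNELS %in% names(object@phaseShifts)))
      return("phaseShifts must cover ccd1..ccd4")
    TRUE
  })

#' @param images named list of four matrices.
#' @param pixelSize object-plane pixel size (um).
#' @param background optional DC level matrix.
#' @param phaseShifts channel-to-delta mapping; the default is the
#'   system's fixed wiring.
#' @rdname HologramSet-class
#' @export
HologramSet <- function(images, pixelSize = 1,
    background = NULL, phaseShifts = .PHASE_SHIFTS) {
  new("HologramSet", images = images[.CHANNELS],
    phaseShifts = phaseShifts, pixelSize = pixelSize,
    background = background)
}

#' Phase map
#'
#' A 2-D phase field in radians. Wrapped maps are confined to
#' `(-pi, pi]`; unwrapped maps are unconstrained. The validity mask marks
#' pixels with measurable fringe modulation.
#'
#' @slot values real matrix (rad).
#' @slot wrapped logical flag.
#' @slot pixelSize object-plane pixel size (um).
#' @slot validity logical matrix or NULL.
#' @slot residues number of phase residues detected (NA if not computed).
#' @exportClass PhaseMap
setClass("PhaseMap",
  representation(values = "matrix", wrapped = "logical",
    pixelSize = "numeric", validity = "ANY", residues = "numeric"),
  validity = function(object) {
    if (object@wrapped) {
      v <- object@values
      if (any(v > pi + 1e-9) || any(v <= -pi - 1e-9))
        return("wrapped phase must lie in (-pi, pi]")
    }
    if (!is.null(object@validity) &&
        !identical(dim(object@validity), dim(object@values)))
      return("validity mask must match values dims")
    TRUE
  })

#' @param values real matrix (rad).
#' @param wrapped logical.
#' @param pixelSize um per pixel.
#' @param validity optional logical matrix.
#' @param residues optional residue count.
#' @rdname PhaseMap-class
#' @export
PhaseMap <- function(values, wrapped = TRUE, pixelSize = 1,
    validity = NULL, residues = NA_real_) {
  new("PhaseMap", values = values, wrapped = wrapped,
    pixelSize = pixelSize, validity = validity, residues = residues)
}

#' Thickness map
#'
#' Physical thickness/height (um) derived from an unwrapped phase map via
#' `dh = lambda * dphi / (2*pi*(n_s - n_m))`, with the indices and
#' wavelength recorded as provenance.
#'
#' @slot values real matrix (um).
#' @slot pixelSize um per pixel.
#' @slot wavelength um.
#' @slot nSample,nMedium refractive indices used for the conversion.
#' @exportClass ThicknessMap
setClass("ThicknessMap",
  representation(values = "matrix", pixelSize = "numeric",
    wavelength = "numeric", nSample = "numeric", nMedium = "numeric"))

#' @param values,pixelSize,wavelength,nSample,nMedium see slots.
#' @rdname ThicknessMap-class
#' @export
ThicknessMap <- function(values, pixelSize = 1, wavelength = 0.532,
    nSample = NA_real_, nMedium = NA_real_) {
  new("ThicknessMap", values = values, pixelSize = pixelSize,
    wavelength = wavelength, nSample = nSample, nMedium = nMedium)
}

#' Channel registration result
#'
#' Estimated geometric relation between the four camera channels. For
#' each channel the `transforms` entry is the *correction* (the affine
#' map that aligns it to the reference; identity for the reference
#' channel) and `misalignment` is its inverse, directly comparable to an
#' injected [MisalignmentModel].
#'
#' @slot reference reference channel id.
#' @slot transforms named list of `list(A = 2x2, b = length-2)`.
#' @slot misalignment named list of decomposed parameters
#'   (`tx`, `ty`, `rot`, `scale`).
#' @slot scores named numeric, final metric value per channel.
#' @slot converged named logical per channel.
#' @slot model,metric character, settings used.
#' @exportClass RegistrationResult
setClass("RegistrationResult",
  representation(reference = "character", transforms = "list",
    misalignment = "list", scores = "numeric", converged = "logical",
    model = "character", metric = "character"),
  validity = function(object) {
    tr <- object@transforms[[object@reference]]
    if (is.null(tr)) return("reference channel missing from transforms")
    if (max(abs(tr$A - diag(2))) > 0 || any(tr$b != 0))
      return("reference channel transform must be the identity")
    TRUE
  })

#' Repeated-measurement summary
#'
#' Holds repeated scalar estimates of one quantity with their mean
#' (reported as the measurement), standard deviation and count.
#'
#' @slot estimates numeric vector.
#' @slot mean,sd,n summary statistics.
#' @exportClass MeasurementSeries
setClass("MeasurementSeries",
  representation(estimates = "numeric", mean = "numeric", sd = "numeric",
    n = "integer"),
  validity = function(object) {
    if (object@n < 1L) return("n must be >= 1")
    if (object@mean < min(object@estimates) - 1e-12 ||
        object@mean > max(object@estimates) + 1e-12)
      return("mean must lie within the range of the estimates")
    TRUE
  })

#' Rectangular region of interest
#'
#' @param row,col top-left corner (1-based pixel indices).
#' @param nrow,ncol extent in pixels (positive).
#' @return an `ROI` object.
#' @export
roi <- function(row, col, nrow, ncol) {
  stopifnot(row >= 1, col >= 1, nrow >= 1, ncol >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
    nrow = as.integer(nrow), ncol = as.integer(ncol)), class = "ROI")
}
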
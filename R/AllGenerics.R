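#' @include AllClasses.R
NULL

#' Optical intensity of a field
#'
#' `|ex|^2 + |ey|^2`, pointwise for matrix-valued fields.
#'
#' @param x a [JonesVector].
#' @return non-negative numeric of the same shape as the components.
#' @examples
#' intensity(jonesVector(1, 1i))  # unit circular field -> 2
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname intensity
setMethod("intensity", "JonesVector",
  function(x) Mod(x@ex)^2 + Mod(x@ey)^2)

#' @rdname hologramImages
#' @export
setGeneric("hologramImages", function(x) standardGeneric("hologramImages"))

#' Accessors for hologram sets
#'
#' @param x a [HologramSet].
#' @return `hologramImages`: named list of the four intensity images;
#'   `phaseShifts`: the channel-to-delta mapping.
#' @export
setMethod("hologramImages", "HologramSet", function(x) x@images)

#' @rdname hologramImages
#' @export
setGeneric("phaseShifts", function(x) standardGeneric("phaseShifts"))

#' @rdname hologramImages
setMethod("phaseShifts", "HologramSet", function(x) x@phaseShifts)

#' Pixel size accessor
#'
#' Object-plane pixel size in micrometres.
#'
#' @param x a map, sample field or hologram set.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname pixelSize
setMethod("pixelSize", "HologramSet", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "SampleField", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "PhaseMap", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "ThicknessMap", function(x) x@pixelSize)

#' Accessors for phase and thickness maps
#'
#' @param x a [PhaseMap] or [ThicknessMap].
#' @return `phaseValues`/`thicknessValues`: the value matrix;
#'   `isWrapped`: logical; `validityMask`: logical matrix or NULL;
#'   `residueCount`: number of phase residues (NA when not computed).
#' @export
setGeneric("phaseValues", function(x) standardGeneric("phaseValues"))
#' @rdname phaseValues
setMethod("phaseValues", "PhaseMap", function(x) x@values)

#' @rdname phaseValues
#' @export
setGeneric("isWrapped", function(x) standardGeneric("isWrapped"))
#' @rdname phaseValues
setMethod("isWrapped", "PhaseMap", function(x) x@wrapped)

#' @rdname phaseValues
#' @export
setGeneric("validityMask", function(x) standardGeneric("validityMask"))
#' @rdname phaseValues
setMethod("validityMask", "PhaseMap", function(x) x@validity)

#' @rdname phaseValues
#' @export
setGeneric("residueCount", function(x) standardGeneric("residueCount"))
#' @rdname phaseValues
setMethod("residueCount", "PhaseMap", function(x) x@residues)

#' @rdname phaseValues
#' @export
setGeneric("thicknessValues", function(x) standardGeneric("thicknessValues"))
#' @rdname phaseValues
setMethod("thicknessValues", "ThicknessMap", function(x) x@values)

#' Accessors for sample fields
#'
#' @param x a [SampleField].
#' @return `transmission`: complex matrix; `truthPhase` /
#'   `truthThickness`: ground-truth matrices; `sampleMeta`: the free-form
#'   metadata list (feature tables for chart targets).
#' @export
setGeneric("transmission", function(x) standardGeneric("transmission"))
#' @rdname transmission
setMethod("transmission", "SampleField", function(x) x@transmission)

#' @rdname transmission
#' @export
setGeneric("truthPhase", function(x) standardGeneric("truthPhase"))
#' @rdname transmission
setMethod("truthPhase", "SampleField", function(x) x@truthPhase)

#' @rdname transmission
#' @export
setGeneric("truthThickness", function(x) standardGeneric("truthThickness"))
#' @rdname transmission
setMethod("truthThickness", "SampleField", function(x) x@truthThickness)

#' @rdname transmission
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
#' @rdname transmission
setMethod("sampleMeta", "SampleField", function(x) x@meta)

#' Accessors for registration results
#'
#' @param x a [RegistrationResult].
#' @return `registrationTransforms`: per-channel correction affines
#'   (`list(A, b)`); `estimatedMisalignment`: decomposed per-channel
#'   misalignment parameters, comparable to an injected
#'   [MisalignmentModel]; `registrationScores`: final metric values.
#' @export
setGeneric("registrationTransforms",
  function(x) standardGeneric("registrationTransforms"))
#' @rdname registrationTransforms
setMethod("registrationTransforms", "RegistrationResult",
  function(x) x@transforms)

#' @rdname registrationTransforms
#' @export
setGeneric("estimatedMisalignment",
  function(x) standardGeneric("estimatedMisalignment"))
#' @rdname registrationTransforms
setMethod("estimatedMisalignment", "RegistrationResult",
  function(x) x@misalignment)

#' @rdname registrationTransforms
#' @export
setGeneric("registrationScores",
  function(x) standardGeneric("registrationScores"))
#' @rdname registrationTransforms
setMethod("registrationScores", "RegistrationResult", function(x) x@scores)

## ---- show methods -------------------------------------------------------

setMethod("show", "JonesVector", function(object) {
  n <- length(object@ex)
  if (n == 1L) {
    cat(sprintf("JonesVector: ex = %s, ey = %s\n",
      format(object@ex), format(object@ey)))
  } else {
    cat(sprintf("JonesVector field: %d x %d pixels\n",
      nrow(object@ex), ncol(object@ex)))
  }
})

setMethod("show", "JonesMatrix", function(object) {
  cat(sprintf("JonesMatrix <%s>\n", object@label))
  print(object@m)
})

setMethod("show", "HologramSet", function(object) {
  d <- dim(object@images[[1L]])
  cat(sprintf("HologramSet: 4 channels, %d x %d px, pixel %.4g um\n",
    d[1L], d[2L], object@pixelSize))
  sh <- object@phaseShifts[.CHANNELS]
  cat("  phase shifts:",
    paste(sprintf("%s=%.4g", names(sh), sh), collapse = ", "), "\n")
})

setMethod("show", "SampleField", function(object) {
  d <- dim(object@transmission)
  cat(sprintf(
    "SampleField: %d x %d px, pixel %.4g um, n_s = %s, n_m = %.4g\n",
    d[1L], d[2L], object@pixelSize, format(object@nSample),
    object@nMedium))
  cat(sprintf("  truth phase range [%.4g, %.4g] rad\n",
    min(object@truthPhase), max(object@truthPhase)))
})

setMethod("show", "PhaseMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("PhaseMap (%s): %d x %d px, range [%.4g, %.4g] rad\n",
    if (object@wrapped) "wrapped" else "unwrapped",
    d[1L], d[2L], min(object@values), max(object@values)))
  if (!is.na(object@residues))
    cat(sprintf("  residues: %d\n", as.integer(object@residues)))
})

setMethod("show", "ThicknessMap", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ThicknessMap: %d x %d px, range [%.4g, %.4g] um (lambda %.4g um, n_s %s, n_m %s)\n",
    d[1L], d[2L], min(object@values), max(object@values),
    object@wavelength, format(object@nSample), format(object@nMedium)))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult (%s model, %s metric, ref %s)\n",
    object@model, object@metric, object@reference))
  for (ch in names(object@misalignment)) {
    p <- object@misalignment[[ch]]
    cat(sprintf(
      "  %s: tx=%.3f ty=%.3f px, rot=%.4f deg, scale=%.5f (score %.3g)\n",
      ch, p$tx, p$ty, p$rot, p$scale, object@scores[[ch]]))
  }
})

setMethod("show", "MeasurementSeries", function(object) {
  cat(sprintf("MeasurementSeries: n = %d, mean = %.6g, sd = %.3g\n",
    object@n, object@mean, object@sd))
})
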
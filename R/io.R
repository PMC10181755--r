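#' @include AllClasses.R
NULL

.tifName <- function(dir, ch) file.path(dir, paste0(ch, ".tif"))

.readGray <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    else stop("hologram TIFFs must be single-channel grayscale: ", path,
      call. = FALSE)
  }
  img
}

#' Read and write four-channel hologram sets
#'
#' A hologram set on disk is a directory of four single-channel TIFFs
#' named `ccd1.tif` .. `ccd4.tif` plus a `metadata.json` sidecar
#' recording the channel-to-phase-shift mapping and pixel size. Integer
#' TIFFs are mapped to `[0, 1]` by their bit-depth full scale (the
#' arctangent reconstruction is scale invariant).
#'
#' @param path directory containing the four TIFFs, or a character
#'   vector of four file paths whose names contain `ccd1`..`ccd4`.
#' @return `readHologramSet`: a [HologramSet].
#' @export
readHologramSet <- function(path) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- vapply(.CHANNELS, function(ch) {
      hit <- list.files(path, pattern = paste0("^", ch, "\\.tiff?$"),
        ignore.case = TRUE, full.names = TRUE)
      if (length(hit)) hit[1L] else NA_character_
    }, character(1))
  } else {
    files <- vapply(.CHANNELS, function(ch) {
      hit <- grep(ch, path, value = TRUE, ignore.case = TRUE)
      if (length(hit)) hit[1L] else NA_character_
    }, character(1))
  }
  if (anyNA(files))
    stop("missing hologram channel(s): ",
      paste(.CHANNELS[is.na(files)], collapse = ", "), call. = FALSE)
  imgs <- lapply(files, .readGray)
  d <- dim(imgs[[1L]])
  for (ch in .CHANNELS)
    if (!identical(dim(imgs[[ch]]), d))
      stop("hologram channel dims differ (", ch, ")", call. = FALSE)
  meta <- NULL
  mpath <- file.path(dirname(files[[1L]]), "metadata.json")
  if (file.exists(mpath)) meta <- jsonlite::read_json(mpath)
  HologramSet(images = imgs,
    pixelSize = if (!is.null(meta$pixelSize)) meta$pixelSize else 1,
    phaseShifts = if (!is.null(meta$phaseShifts))
      unlist(meta$phaseShifts)[.CHANNELS] else .PHASE_SHIFTS)
}

#' @param holos a [HologramSet]; intensities are clipped to `[0, 1]`
#'   before integer encoding.
#' @param dir output directory (created if needed).
#' @param bitDepth 8 or 16.
#' @return `writeHologramSet`: `dir`, invisibly.
#' @rdname readHologramSet
#' @export
writeHologramSet <- function(holos, dir, bitDepth = 16L) {
  stopifnot(bitDepth %in% c(8L, 16L))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in .CHANNELS) {
    img <- pmin(pmax(hologramImages(holos)[[ch]], 0), 1)
    tiff::writeTIFF(img, .tifName(dir, ch),
      bits.per.sample = as.integer(bitDepth))
  }
  jsonlite::write_json(list(pixelSize = pixelSize(holos),
    phaseShifts = as.list(phaseShifts(holos)),
    bitDepth = bitDepth), file.path(dir, "metadata.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read and write floating-point maps
#'
#' Phase and thickness maps are written as 32-bit float TIFFs,
#' normalized to `[0, 1]` with the affine restore parameters (and the
#' map kind and geometry) stored in a JSON sidecar next to the image.
#'
#' @param x a [PhaseMap], [ThicknessMap] or plain matrix.
#' @param path output TIFF path (the sidecar gets `.json` appended).
#' @return `writeMap`: `path` invisibly; `readMap`: the restored object
#'   (a plain matrix when no sidecar is present).
#' @export
writeMap <- function(x, path) {
  v <- x
  side <- list(kind = "matrix")
  if (is(x, "PhaseMap")) {
    v <- phaseValues(x)
    side <- list(kind = "phase", wrapped = isWrapped(x),
      pixelSize = pixelSize(x), residues = residueCount(x))
  } else if (is(x, "ThicknessMap")) {
    v <- thicknessValues(x)
    side <- list(kind = "thickness", pixelSize = pixelSize(x),
      wavelength = x@wavelength, nSample = x@nSample,
      nMedium = x@nMedium)
  }
  off <- min(v); sc <- max(v) - off
  if (sc == 0) sc <- 1
  side$offset <- off; side$scale <- sc
  tiff::writeTIFF((v - off) / sc, path, bits.per.sample = 32L)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' @rdname writeMap
#' @export
readMap <- function(path) {
  v <- .readGray(path)
  spath <- paste0(path, ".json")
  if (!file.exists(spath)) return(v)
  side <- jsonlite::read_json(spath)
  v <- v * side$scale + side$offset
  switch(side$kind,
    phase = PhaseMap(values = v, wrapped = isTRUE(side$wrapped),
      pixelSize = side$pixelSize,
      residues = if (is.null(side$residues)) NA_real_
        else as.numeric(side$residues)),
    thickness = ThicknessMap(values = v, pixelSize = side$pixelSize,
      wavelength = side$wavelength,
      nSample = as.numeric(side$nSample),
      nMedium = as.numeric(side$nMedium)),
    v)
}

## ---- run configuration --------------------------------------------------

#' Run configuration
#'
#' Nested-list configuration covering the optical system, noise and
#' misalignment models, sample description, registration and
#' measurement settings. `loadRunConfig` merges a (possibly partial)
#' YAML file over the defaults, so every field is explicit after
#' loading; `saveRunConfig` round-trips losslessly.
#'
#' @return `defaultRunConfig`: the complete default configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    optics = list(wavelength_um = 0.532, na = 0.25, magnification = 10,
      pixel_pitch_um = 3.45, dims = c(512L, 512L),
      amplitude_object = 1, amplitude_reference = 1, bit_depth = 12L,
      arm_phase_offset = 0.4, pupil = TRUE),
    noise = list(enabled = TRUE, shot_noise = TRUE,
      read_noise_sigma = 3, photon_scale = 2000),
    misalignment = list(
      enabled = TRUE,
      ccd2 = list(tx = 3.2, ty = -1.7, rot = 0.3, scale = 1),
      ccd3 = list(tx = -2.1, ty = 1.4, rot = -0.2, scale = 1),
      ccd4 = list(tx = 1.2, ty = 2.6, rot = 0.45, scale = 1)),
    sample = list(type = "usaf",
      heights_um = c(0.2138, 0.3215, 0.3855),
      elements = list(c(7L, 1L)), n_sample = 1.52, n_medium = 1.0,
      bead_diameter_um = 10, bead_n = 1.49, oil_n = 1.51,
      n_frames = 1L, velocity_um_s = 5, fps = 30),
    registration = list(model = "rigid", metric = "ncc", levels = 3L,
      reference = "ccd1", use_texture_target = TRUE),
    measure = list(step_inner = 0.6, contrast_threshold = 0.2,
      bead_window = 15L))
}

.mergeConfig <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(base[[nm]]) && is.list(extra[[nm]]) &&
        !is.null(names(extra[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], extra[[nm]])
    else base[[nm]] <- extra[[nm]]
  }
  base
}

.validateConfig <- function(config) {
  o <- config$optics
  for (f in c("wavelength_um", "na", "magnification", "pixel_pitch_um"))
    if (!is.numeric(o[[f]]) || o[[f]] <= 0)
      stop("invalid config: optics$", f, " must be a positive number",
        call. = FALSE)
  if (length(o$dims) != 2L || any(o$dims < 8))
    stop("invalid config: optics$dims must be two sizes >= 8",
      call. = FALSE)
  if (!config$sample$type %in% c("usaf", "beads", "texture", "empty"))
    stop("invalid config: sample$type must be one of usaf, beads, ",
      "texture, empty", call. = FALSE)
  config
}

#' @param path YAML file path.
#' @rdname defaultRunConfig
#' @export
loadRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  .validateConfig(.mergeConfig(defaultRunConfig(),
    if (is.null(user)) list() else user))
}

#' @param config a configuration list.
#' @rdname defaultRunConfig
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
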
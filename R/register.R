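#' @include AllClasses.R utils.R
NULL

.zscore <- function(x) {
  s <- sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

## Integer translation initial guess by FFT cross-correlation (on
## magnitude, so channels with inverted contrast still lock on).
.xcorrShift <- function(fixed, moving) {
  nr <- nrow(fixed); nc <- ncol(fixed)
  f <- .zscore(fixed); m <- .zscore(moving)
  cc <- Re(fft(Conj(fft(m)) * fft(f), inverse = TRUE))
  k <- which.max(abs(cc)) - 1L
  dy <- k %% nr; dx <- k %/% nr
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  ## peak at j corresponds to moving = fixed shifted by -j; the
  ## aligning correction is the opposite shift
  c(-dx, -dy)
}

.regParams <- function(model) switch(model,
  translation = 2L, rigid = 3L, similarity = 4L, affine = 6L,
  stop("unknown registration model '", model, "'", call. = FALSE))

.parToAffine <- function(par, model) {
  if (model == "affine") {
    A <- diag(2) + matrix(par[3:6], 2, 2)
    list(A = A, b = par[1:2])
  } else {
    paramsToAffine(par[1], par[2],
      rot = if (length(par) >= 3) par[3] else 0,
      scale = if (length(par) >= 4) exp(par[4]) else 1)
  }
}

.regMetric <- function(w, f, metric) {
  if (metric == "ncc") {
    r <- suppressWarnings(cor(as.vector(w), as.vector(f)))
    if (is.na(r)) return(1)
    1 - r * r
  } else {
    mean((w - f)^2)
  }
}

#' One-time intensity-based registration of the four channels
#'
#' Estimates, for each non-reference channel, the geometric transform
#' that aligns it with the reference channel by maximizing an intensity
#' similarity metric through a multi-resolution pyramid: block-mean
#' downsampled levels are registered coarse-to-fine, each level refined
#' with Nelder-Mead over the transform parameters, starting from an FFT
#' cross-correlation translation estimate. Registration only needs to
#' be performed once per camera arrangement; the result is reusable
#' across acquisitions via [applyRegistration()].
#'
#' The default metric is normalized cross-correlation (`1 - r^2`),
#' which is invariant to the inverted fringe contrast of quadrature
#' channels; plain mean-squared difference is available as `"msd"` for
#' channels with matched contrast.
#'
#' @param holos a [HologramSet].
#' @param reference reference channel id (default `"ccd1"`).
#' @param model transform class: `"translation"`, `"rigid"`
#'   (translation + rotation), `"similarity"` (+ isotropic scale) or
#'   `"affine"`.
#' @param metric `"ncc"` or `"msd"`.
#' @param levels pyramid levels (>= 1).
#' @param maxit Nelder-Mead iteration budget per level
#'   (coarse to fine; recycled).
#' @param crop border fraction excluded from the metric.
#' @param presmooth box-filter width applied to both images before
#'   optimization (1 disables); smoothing regularizes the similarity
#'   landscape under camera noise at negligible cost in precision.
#' @return a [RegistrationResult]. Non-convergence of the optimizer is
#'   flagged per channel in its `converged` slot (best-so-far transform
#'   retained) and raises a warning.
#' @export
registerChannels <- function(holos, reference = "ccd1",
    model = c("rigid", "translation", "similarity", "affine"),
    metric = c("ncc", "msd"), levels = 3L,
    maxit = c(500L, 400L, 300L), crop = 0.08, presmooth = 3L) {
  model <- match.arg(model)
  metric <- match.arg(metric)
  imgs <- hologramImages(holos)
  if (presmooth > 1L) imgs <- lapply(imgs, boxFilter, as.integer(presmooth))
  stopifnot(reference %in% names(imgs))
  maxit <- rep_len(maxit, levels)
  npar <- .regParams(model)

  pyramid <- function(img) {
    out <- vector("list", levels)
    out[[1L]] <- img
    for (l in seq_len(levels - 1L)) out[[l + 1L]] <- downsample2(out[[l]])
    rev(out)   # coarse first
  }
  fpyr <- pyramid(imgs[[reference]])

  transforms <- list()
  misalign <- list()
  scores <- numeric(0)
  converged <- logical(0)
  for (ch in .CHANNELS) {
    if (ch == reference) {
      transforms[[ch]] <- identityAffine()
      next
    }
    mpyr <- pyramid(imgs[[ch]])
    sh <- .xcorrShift(fpyr[[1L]], mpyr[[1L]])
    par <- c(sh, rep(0, npar - 2L))
    ok <- TRUE
    val <- NA_real_
    for (l in seq_len(levels)) {
      f <- fpyr[[l]]; m <- mpyr[[l]]
      marg <- max(4L, round(crop * min(dim(f))))
      ri <- (marg + 1L):(nrow(f) - marg)
      ci <- (marg + 1L):(ncol(f) - marg)
      fr <- f[ri, ci]
      obj <- function(p) {
        tr <- .parToAffine(p, model)
        w <- warpImage(m, tr$A, tr$b)
        .regMetric(w[ri, ci], fr, metric)
      }
      fit <- optim(par, obj, method = "Nelder-Mead",
        control = list(maxit = maxit[l], reltol = 1e-9))
      par <- fit$par
      val <- fit$value
      if (l == levels) ok <- fit$convergence == 0L
      if (l < levels) {
        par[1:2] <- par[1:2] * 2          # translation scales with level
        if (model == "affine") par[1:2] <- par[1:2]
      }
    }
    if (!ok)
      warning("registration of ", ch,
        " did not fully converge; best-so-far transform returned",
        call. = FALSE)
    tr <- .parToAffine(par, model)
    transforms[[ch]] <- tr
    misalign[[ch]] <- decomposeAffine(invertAffine(tr))
    scores[[ch]] <- val
    converged[[ch]] <- ok
  }
  new("RegistrationResult", reference = reference,
    transforms = transforms, misalignment = misalign, scores = scores,
    converged = converged, model = model, metric = metric)
}

#' Apply cached registration transforms to a hologram set
#'
#' Resamples each non-reference channel with its correction transform so
#' all four images are in pixelwise correspondence.
#'
#' @param holos a [HologramSet].
#' @param reg a [RegistrationResult] (typically computed once on a
#'   registration acquisition and reused).
#' @return the aligned [HologramSet].
#' @export
applyRegistration <- function(holos, reg) {
  stopifnot(is(reg, "RegistrationResult"))
  imgs <- hologramImages(holos)
  for (ch in names(imgs)) {
    if (ch == reg@reference) next
    tr <- reg@transforms[[ch]]
    if (is.null(tr)) next
    imgs[[ch]] <- warpImage(imgs[[ch]], tr$A, tr$b)
  }
  initialize(holos, images = imgs, background = NULL)
}
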
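#' @include AllClasses.R
NULL

#' USAF 1951 line width
#'
#' Standard resolution-target geometry: element `e` of group `g` has
#' line width `500 / 2^(g + (e - 1)/6)` micrometres.
#'
#' @param group,element integers (element 1..6).
#' @return line width in um.
#' @examples
#' usafLinewidth(8, 4)  # 1.381 um
#' @export
usafLinewidth <- function(group, element)
  500 / 2^(group + (element - 1) / 6)

## Local maxima of a numeric vector, plateau-aware (a flat top counts
## once, at its centre).
.localMaxima <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (i in seq_len(k)) {
    left <- if (i > 1L) r$values[i - 1L] else -Inf
    right <- if (i < k) r$values[i + 1L] else -Inf
    if (r$values[i] > left && r$values[i] > right)
      out <- c(out, (starts[i] + ends[i]) %/% 2L)
  }
  out
}

.movavg <- function(v, k) {
  if (k <= 1L) return(v)
  n <- length(v)
  h <- (k - 1L) %/% 2L
  vp <- c(rep(v[1L], h), v, rep(v[n], h))
  as.numeric(stats::filter(vp, rep(1 / k, k), sides = 2))[h + seq_len(n)]
}

#' Three-bar resolvability of a profile
#'
#' Decides whether a 1-D phase profile across a three-bar chart element
#' shows three resolved bars: after range normalization, three local
#' maxima must be present and the mean peak-to-dip modulation (peak
#' height minus the interleaved minima, in normalized units) must reach
#' the contrast threshold.
#'
#' @param profile numeric vector of phase (or height) samples crossing
#'   all three bars, or the data.frame from [extractProfile()].
#' @param threshold modulation threshold (default 0.2).
#' @param smooth moving-average width applied before peak detection.
#' @return list with `resolvable` (logical), `contrast` (0 when fewer
#'   than three peaks are found) and `nPeaks`.
#' @export
resolvable <- function(profile, threshold = 0.2, smooth = 3L) {
  if (is.data.frame(profile)) profile <- profile$value
  rng <- range(profile)
  if (diff(rng) < .Machine$double.eps^0.5)
    return(list(resolvable = FALSE, contrast = 0, nPeaks = 0L))
  pn <- (profile - rng[1L]) / diff(rng)
  pn <- .movavg(pn, smooth)
  pk <- .localMaxima(pn)
  if (length(pk) < 3L)
    return(list(resolvable = FALSE, contrast = 0,
      nPeaks = length(pk)))
  pk <- pk[order(pn[pk], decreasing = TRUE)][1:3]
  pk <- sort(pk)
  dips <- vapply(1:2, function(i) min(pn[pk[i]:pk[i + 1L]]), numeric(1))
  contrast <- mean(pn[pk]) - mean(dips)
  list(resolvable = contrast >= threshold, contrast = contrast,
    nPeaks = length(.localMaxima(pn)))
}

.roiValues <- function(values, r) {
  stopifnot(inherits(r, "ROI"))
  d <- dim(values)
  if (r$row + r$nrow - 1L > d[1L] || r$col + r$ncol - 1L > d[2L])
    stop("ROI exceeds image bounds", call. = FALSE)
  values[r$row + seq_len(r$nrow) - 1L, r$col + seq_len(r$ncol) - 1L,
    drop = FALSE]
}

.roiOverlap <- function(a, b) {
  max(0L, min(a$row + a$nrow, b$row + b$nrow) - max(a$row, b$row)) > 0 &&
  max(0L, min(a$col + a$ncol, b$col + b$ncol) - max(a$col, b$col)) > 0
}

#' ROI step height
#'
#' Height of a chart feature over the substrate: mean thickness inside
#' the feature ROI minus mean thickness inside the substrate ROI.
#'
#' @param thickness a [ThicknessMap] (or plain matrix, um).
#' @param feature,substrate disjoint [roi()]s.
#' @return step height in um.
#' @export
stepHeight <- function(thickness, feature, substrate) {
  v <- if (is(thickness, "ThicknessMap")) thicknessValues(thickness)
    else thickness
  if (.roiOverlap(feature, substrate))
    stop("feature and substrate ROIs overlap", call. = FALSE)
  mean(.roiValues(v, feature)) - mean(.roiValues(v, substrate))
}

#' Summarize repeated measurements
#'
#' @param estimates numeric vector of repeated scalar estimates (n >= 1).
#' @return a [MeasurementSeries]; its mean is the reported measurement.
#' @export
repeatStats <- function(estimates) {
  if (length(estimates) == 0L)
    stop("no estimates supplied", call. = FALSE)
  s <- if (length(estimates) > 1L) sd(estimates) else 0
  new("MeasurementSeries", estimates = as.numeric(estimates),
    mean = mean(estimates), sd = s, n = length(estimates))
}

#' Peak phase of a bead
#'
#' Magnitude of the phase extremum of a bead in an unwrapped phase map.
#' Within a window around the supplied centre hint, the *squared* phase
#' magnitude is box-smoothed and fitted with a local paraboloid around
#' its maximum: for a spherical bead the squared phase profile
#' `phi0^2 * (1 - rho^2 / r^2)` is exactly quadratic in the in-plane
#' radius, so the fit has no model error regardless of the bead size,
#' while the smoothing suppresses the upward bias a raw maximum of a
#' noisy field would carry. The constant offset the box filter adds to
#' a quadratic (its kernel variance times the curvature trace) is
#' removed exactly before taking the square root. Paired with
#' [phaseToThickness()] this yields the bead thickness.
#'
#' @param phase an unwrapped [PhaseMap].
#' @param center `c(row, col)` pixel hint; `NULL` = map centre.
#' @param window half-size of the search window (px).
#' @param smooth box-filter width (px; 1 disables).
#' @param fitWindow half-size of the paraboloid fit neighbourhood (px).
#' @param fit use the paraboloid apex fit (otherwise the smoothed max).
#' @return peak `|phase|` in rad.
#' @export
beadPeakPhase <- function(phase, center = NULL, window = 15L,
    smooth = 3L, fitWindow = 4L, fit = TRUE) {
  stopifnot(is(phase, "PhaseMap"))
  if (isWrapped(phase))
    warning("bead peak read from a wrapped phase map", call. = FALSE)
  v <- abs(phaseValues(phase))
  d <- dim(v)
  if (is.null(center)) center <- (d + 1) / 2
  ri <- max(1L, round(center[1L]) - window):
    min(d[1L], round(center[1L]) + window)
  ci <- max(1L, round(center[2L]) - window):
    min(d[2L], round(center[2L]) + window)
  if (!length(ri) || !length(ci))
    stop("empty search window", call. = FALSE)
  w <- boxFilter(v[ri, ci, drop = FALSE]^2, smooth)
  mi <- which(w == max(w), arr.ind = TRUE)[1L, ]
  peak0 <- sqrt(max(w[mi[1L], mi[2L]], 0))
  if (!fit) return(peak0)
  h <- as.integer(fitWindow)
  rr <- (mi[1L] - h):(mi[1L] + h)
  cc <- (mi[2L] - h):(mi[2L] + h)
  if (min(rr) < 1L || min(cc) < 1L || max(rr) > nrow(w) ||
      max(cc) > ncol(w))
    return(peak0)
  z <- as.vector(w[rr, cc])
  x <- rep(-h:h, each = 2L * h + 1L)
  y <- rep(-h:h, times = 2L * h + 1L)
  co <- coef(lm(z ~ y + x + I(y^2) + I(y * x) + I(x^2)))
  H <- matrix(c(2 * co[4L], co[5L], co[5L], 2 * co[6L]), 2, 2)
  g <- c(co[2L], co[3L])
  if (any(!is.finite(H)) || det(H) <= 0 || H[1L, 1L] >= 0)
    return(peak0)
  p <- -solve(H, g)
  if (any(abs(p) > h)) return(peak0)
  apex <- as.numeric(co[1L] + sum(g * p) + 0.5 * sum(p * (H %*% p)))
  ## the box filter raises/lowers a quadratic by its kernel variance
  ## times the curvature; undo that offset exactly
  kvar <- (smooth^2 - 1) / 12
  sqrt(max(unname(apex - kvar * (co[4L] + co[6L])), 0))
}

#' Sample a map along a line segment
#'
#' Bilinear profile extraction between two points, for three-bar
#' resolvability checks and bead cross-sections.
#'
#' @param map a [PhaseMap], [ThicknessMap] or plain matrix.
#' @param from,to endpoints `c(row, col)` in pixels.
#' @param n number of samples (default: 2 per pixel of length).
#' @return data.frame with `distance` (um for maps, px for matrices)
#'   and `value`.
#' @export
extractProfile <- function(map, from, to, n = NULL) {
  v <- if (is(map, "PhaseMap")) phaseValues(map)
    else if (is(map, "ThicknessMap")) thicknessValues(map)
    else map
  px <- if (is(map, "PhaseMap") || is(map, "ThicknessMap"))
    pixelSize(map) else 1
  len <- sqrt(sum((to - from)^2))
  if (is.null(n)) n <- max(2L, ceiling(2 * len))
  tfrac <- seq(0, 1, length.out = n)
  rr <- from[1L] + tfrac * (to[1L] - from[1L])
  cc <- from[2L] + tfrac * (to[2L] - from[2L])
  data.frame(distance = tfrac * len * px,
    value = bilinearSample(v, x = cc, y = rr))
}
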
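#' Wrap phase values into (-pi, pi]
#'
#' @param x numeric vector/matrix of phase values (rad).
#' @return values congruent to `x` modulo `2*pi`, in `(-pi, pi]`.
#' @examples
#' wrapToPi(6.0)   # 6 - 2*pi
#' wrapToPi(pi)    # stays pi
#' @export
wrapToPi <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

## FFT sample frequencies (cycles per unit), numpy-style ordering.
fftFreq <- function(n, d = 1) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

## Bilinear sampling of matrix `img` at fractional coordinates
## (x = column, y = row), with replicate padding (coordinates clamped).
bilinearSample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L)
  y0 <- pmin(floor(y), nr - 1L)
  if (nc == 1L) x0 <- pmax(x0, 1L)
  if (nr == 1L) y0 <- pmax(y0, 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + (x0 - 1) * nr
  v00 <- img[i00]
  v01 <- img[i00 + nr]
  v10 <- img[i00 + 1]
  v11 <- img[i00 + nr + 1]
  (1 - fy) * (1 - fx) * v00 + (1 - fy) * fx * v01 +
    fy * (1 - fx) * v10 + fy * fx * v11
}

## Affine maps on pixel coordinates about the image centre:
##   p' = A %*% (p - c) + c + b,   p = (x, y)
## `warpImage` resamples: out[p] = img[map(p)] (bilinear, replicate pad).
warpImage <- function(img, A, b = c(0, 0)) {
  nr <- nrow(img); nc <- ncol(img)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  xs <- rep(seq_len(nc), each = nr) - cx
  ys <- rep.int(seq_len(nr), nc) - cy
  xp <- A[1, 1] * xs + A[1, 2] * ys + cx + b[1]
  yp <- A[2, 1] * xs + A[2, 2] * ys + cy + b[2]
  matrix(bilinearSample(img, xp, yp), nr, nc)
}

## (tx, ty, rot [deg], scale) -> (A, b)
paramsToAffine <- function(tx = 0, ty = 0, rot = 0, scale = 1) {
  th <- rot * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  list(A = A, b = c(tx, ty))
}

invertAffine <- function(tr) {
  Ai <- solve(tr$A)
  list(A = Ai, b = as.numeric(-Ai %*% tr$b))
}

## Decompose a similarity affine into (tx, ty, rot, scale).
decomposeAffine <- function(tr) {
  s <- sqrt(abs(det(tr$A)))
  list(tx = tr$b[1], ty = tr$b[2],
    rot = atan2(tr$A[2, 1], tr$A[1, 1]) * 180 / pi, scale = s)
}

identityAffine <- function() list(A = diag(2), b = c(0, 0))

## 2x block-mean downsampling (trailing odd row/col dropped).
downsample2 <- function(img) {
  nr <- nrow(img) %/% 2L * 2L; nc <- ncol(img) %/% 2L * 2L
  x <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  (x[seq(1L, nr, 2L), seq(1L, nc, 2L), drop = FALSE] +
   x[seq(2L, nr, 2L), seq(1L, nc, 2L), drop = FALSE] +
   x[seq(1L, nr, 2L), seq(2L, nc, 2L), drop = FALSE] +
   x[seq(2L, nr, 2L), seq(2L, nc, 2L), drop = FALSE]) / 4
}

## k x k box (mean) filter with replicate padding; k odd.
boxFilter <- function(img, k = 3L) {
  if (k <= 1L) return(img)
  h <- (k - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr + 2L * h) - h, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * h) - h, 1L), nc)
  p <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L))
    out <- out + p[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
  out / (k * k)
}

## Smooth pseudo-random field in [0, 1]: white noise low-passed by a
## Gaussian of s.d. `corLen` pixels in the spatial domain, then rescaled.
smoothRandomField <- function(dims, corLen = 8) {
  nr <- dims[1L]; nc <- dims[2L]
  w <- matrix(rnorm(nr * nc), nr, nc)
  fy <- fftFreq(nr); fx <- fftFreq(nc)
  h <- exp(-2 * pi^2 * corLen^2 * outer(fy^2, fx^2, "+"))
  f <- Re(fft(fft(w) * h, inverse = TRUE)) / (nr * nc)
  (f - min(f)) / (max(f) - min(f))
}
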
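#' @include AllClasses.R utils.R
NULL

## Orthonormal DCT-II matrix of size n, cached per size. The
## least-squares unwrapper applies it as dense matrix products (BLAS);
## for the image sizes this package targets that is faster to get right
## than an FFT factorization and costs well under a second at 512^2.
.dctCache <- new.env(parent = emptyenv())
dctMatrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dctCache[[key]])) return(.dctCache[[key]])
  k <- 0:(n - 1L)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1L, ] <- C[1L, ] / sqrt(2)
  .dctCache[[key]] <- C
  C
}

#' Minimum-norm (least-squares) phase unwrapping
#'
#' Unweighted least-squares unwrapping: the unwrapped surface is the
#' minimizer of the L2 mismatch between its gradients and the wrapped
#' gradients of the input, obtained by solving the discrete Poisson
#' equation with Neumann boundary conditions in a cosine-transform
#' basis. For residue-free inputs the result equals the true phase up
#' to a constant; the solver always returns, and the number of phase
#' residues (a quality indicator: 0 means the wrapped gradients are
#' consistent) is recorded in the result's `residues` slot.
#'
#' The free additive constant is fixed so that the output agrees with
#' the wrapped input modulo 2*pi in the circular-mean sense, which pins
#' a zero-phase background at zero.
#'
#' @param phase a wrapped [PhaseMap].
#' @return an unwrapped [PhaseMap] (validity mask carried over).
#' @examples
#' ramp <- wrapToPi(outer(rep(0, 32), 0.5 * (1:32)))
#' u <- unwrapPhase(PhaseMap(ramp))
#' residueCount(u)  # 0
#' @export
unwrapPhase <- function(phase) {
  stopifnot(is(phase, "PhaseMap"))
  if (!isWrapped(phase)) return(phase)
  psi <- phaseValues(phase)
  nr <- nrow(psi); nc <- ncol(psi)

  dx <- wrapToPi(psi[, -1L, drop = FALSE] - psi[, -nc, drop = FALSE])
  dy <- wrapToPi(psi[-1L, , drop = FALSE] - psi[-nr, , drop = FALSE])

  ## residues: circulation of wrapped gradients around each 2x2 loop
  res <- 0L
  if (nr > 1L && nc > 1L) {
    loop <- dx[-nr, , drop = FALSE] + dy[, -1L, drop = FALSE] -
      dx[-1L, , drop = FALSE] - dy[, -nc, drop = FALSE]
    res <- sum(abs(round(loop / (2 * pi))) > 0)
  }

  ## divergence of the wrapped gradient field (Neumann boundaries)
  Dx <- cbind(dx, 0); Dy <- rbind(dy, 0)
  rho <- (Dx - cbind(0, Dx[, -nc, drop = FALSE])) +
         (Dy - rbind(0, Dy[-nr, , drop = FALSE]))

  Cr <- dctMatrix(nr); Cc <- dctMatrix(nc)
  rhat <- Cr %*% rho %*% t(Cc)
  eig <- outer(2 * cos(pi * (0:(nr - 1L)) / nr) - 2,
               2 * cos(pi * (0:(nc - 1L)) / nc) - 2, "+")
  eig[1L, 1L] <- 1
  phat <- rhat / eig
  phat[1L, 1L] <- 0
  phi <- t(Cr) %*% phat %*% Cc

  offset <- Arg(mean(exp(1i * (psi - phi))))
  initialize(phase, values = phi + offset, wrapped = FALSE,
    residues = as.numeric(res))
}
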
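# Fixture builders shared across the test files. Smooth fields are
# built from low-order sinusoids so they stay independent of the
# package's own texture generator.

smoothField <- function(dims, scale = 1) {
  nr <- dims[1L]; nc <- dims[2L]
  xs <- seq(0, 1, length.out = nc)
  ys <- seq(0, 1, length.out = nr)
  m <- matrix(0, nr, nc)
  for (k in 1:3) for (l in 1:3)
    m <- m + rnorm(1) *
      outer(sin(pi * k * ys + runif(1, 0, 2 * pi)),
            sin(pi * l * xs + runif(1, 0, 2 * pi)))
  scale * m / max(abs(m))
}

# A random smooth complex sample with amplitude texture and phase in
# roughly [-maxPhase, maxPhase].
randomSmoothSample <- function(dims = c(16L, 16L), pixelSize = 0.345,
    maxPhase = 3) {
  alpha <- pmin(0.55 + 0.45 * smoothField(dims), 1)
  alpha <- pmax(alpha, 0.05)
  phase <- smoothField(dims, scale = maxPhase)
  SampleField(transmission = alpha * exp(1i * phase),
    pixelSize = pixelSize, truthPhase = phase,
    truthThickness = matrix(0, dims[1L], dims[2L]),
    nSample = NA_real_, nMedium = 1, meta = list())
}

# Misalignment used by the recovery tests (translations <= 5 px,
# rotations <= 1 degree).
testMisalignment <- function() {
  MisalignmentModel(
    ccd2 = list(tx = 3.2, ty = -1.7, rot = 0.3),
    ccd3 = list(tx = -2.1, ty = 1.4, rot = -0.2),
    ccd4 = list(tx = 1.2, ty = 2.6, rot = 0.45))
}

maxAbs <- function(x) max(abs(x))
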
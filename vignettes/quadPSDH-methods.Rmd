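---
title: "Four-channel synchronous phase-shifting holography: model and methods"
author: "quadPSDH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-channel synchronous phase-shifting holography: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadPSDH)
```

## The optical model

The system is a Mach–Zehnder interferometer in which object and
reference arms each pass a 45° linear polarizer and a quarter-wave
plate, recombine in a polarizing beamsplitter (PBS), traverse a 45°
quarter-wave plate, and are finally split by a second PBS onto four
cameras. The polarization network realizes four simultaneous reference
phase shifts — 0 and π on the first camera pair, π/2 and 3π/2 on the
second — so a single exposure yields a complete four-step
phase-shifting measurement. That is what makes the method *synchronous*:
nothing moves between the four holograms, so moving samples can be
imaged at the camera frame rate.

`propagateSystem()` implements this chain literally with the 2×2 Jones
operators from `elementMatrix()`, and `closedFormIntensities()`
implements the closed form it reduces to,

$$I_{1,2} = \tfrac14\left[\alpha^2 A_O^2 + A_R^2 \pm 2\alpha A_O A_R
\cos\Delta\varphi\right],\qquad
I_{3,4} = \tfrac14\left[\alpha^2 A_O^2 + A_R^2 \pm 2\alpha A_O A_R
\sin\Delta\varphi\right].$$

The two are held equal to machine precision by a property test; the
closed form is the algebraic oracle for the chain.

Two normalization conventions deserve an explicit statement, because
the printed element matrices are unnormalized:

* the object-arm quarter-wave plate is aligned with the 45° polarization
  passing through it, so it leaves the polarization state unchanged;
  applying its matrix multiplies the field by the eigenvalue $(1-i)$,
  a global amplitude/phase factor that the model drops (energy loss and
  global phase are ignored throughout, and phase retrieval is a ratio
  of intensity differences, so global scale cancels);
* the ½ amplitude prefactor of the PBS matrices is applied at the
  *first* PBS passage, where the recombined beam is genuinely split;
  the final PBS only routes the already-separated orthogonal components
  to their cameras and uses the bare projection matrices
  (`elementMatrix(..., prefactor = "unit")`). Applying ½ twice would
  scale every channel by an extra ¼ without changing any retrieved
  phase, but the ¼ coefficients above are the convention the package
  commits to.

The two printed 45° wave-plate matrices (fast-axis and slow-axis
orientation) are kept as distinct element constants rather than derived
from one general retarder rotation formula, which avoids committing to
a sign convention the element set never exercises.

The complex-amplitude phasor convention is $e^{+j\varphi}$, and no
inter-element propagation phase is added: the design premise of the
instrument is that both arms traverse identical optics with equal path
lengths. The residual global arm offset $\varphi_o - \varphi_r$ is a
configuration scalar (`armPhaseOffset`, default 0.4 rad in the
file-based workflow) and is removed by calibration subtraction, which
is exactly how the physical instrument deals with it.

## Samples and ground truth

All generators return a `SampleField` carrying the complex transmission
together with ground-truth phase and thickness maps obeying
$\varphi = (2\pi/\lambda)(n_s - n_m)\,\Delta h$ pointwise.

* `usafPhaseTarget()` builds phase-only USAF 1951 chart blocks (three
  vertical bars, three horizontal bars, a square pad) at the standard
  geometry: line width $w = 500/2^{g+(e-1)/6}$ µm, bar length $5w$,
  pitch $2w$. Edges are anti-aliased by exact pixel-area coverage by
  default — with binary edges, staircase quantization would dominate
  sub-nanometre step-height comparisons — and a `antialias = FALSE`
  flag provides exact binary rasterization for oracle tests. The
  defaults (etch heights 213.8/321.5/385.5 nm, substrate index 1.52 in
  air, λ = 532 nm) describe a manufactured quantitative-phase chart.
* `beadField()` projects spheres: thickness
  $t(\rho) = 2\sqrt{(d/2)^2-\rho^2}$, summed over overlapping beads.
  The default bead is a 10 µm PMMA pellet (n = 1.49) in 1.51 oil, i.e.
  a *negative* index contrast: the phase is signed by $(n_s - n_m)$,
  and the thickness conversion uses the signed contrast so physical
  heights come out positive on either side of the medium index.
* `movingBeadSequence()` translates a bead along +y (down, in image
  coordinates with the origin at the top-left) at constant velocity —
  a pellet sinking under gravity. The velocity is a free parameter
  (the sedimentation speed is not a property of the optical system);
  frames that clip the boundary warn but are produced.
* `textureTarget()` is a zero-phase scene with smooth pseudo-random
  amplitude texture, used as the registration acquisition (next
  section).

## Degradation model

The camera model (`NoiseModel`, applied by `corruptHolograms()`) is
Poisson shot noise on expected photon counts, additive Gaussian read
noise, and quantization to the camera bit depth with clipping at full
scale. Defaults describe a 12-bit machine-vision camera exposed to
about half well at unit intensity: `photonScale = 2000` expected counts
at intensity 1, read noise 3 counts. Per-channel misalignment
(`MisalignmentModel`) is an affine resampling — translation, rotation
about the image centre, isotropic scale — applied to cameras 2–4
*after* intensity formation, because four physically distinct cameras
view the same optical field through different geometric mappings. The
default misalignments (a few pixels, fractions of a degree) are of the
size a carefully aligned four-camera bench still cannot avoid, which is
why the method requires registration at all.

`applyPupil()` models the finite aperture: the complex field is
low-passed by a circular coherent transfer function of radius
NA/λ in spatial frequency. With the default 0.25 aperture at 532 nm the
cutoff is 0.47 cycles/µm, i.e. a two-point resolution of
γ = λ/(2NA) = 1.064 µm; chart elements with line widths below roughly
this scale lose their three-bar modulation, which is what the
`resolvable()` metric quantifies.

## Reconstruction pipeline

**Registration.** The four cameras are registered once per arrangement
(`registerChannels()`), and the cached transforms are reused for every
subsequent acquisition (`applyRegistration()`). The estimator is a
multi-resolution pyramid (block-mean downsampling, coarse-to-fine),
initialized by FFT cross-correlation and refined per level by
Nelder-Mead over the transform parameters. Two deliberate choices:

* *Metric.* The default similarity metric is normalized
  cross-correlation ($1-r^2$), not mean-squared difference. The four
  channels are in exact quadrature: on a pure-phase scene camera 2
  records the *contrast-inverted* image of camera 1
  ($I_2 = \mathrm{const} - I_1$), so a mean-squared metric is
  maximized, not minimized, at alignment. NCC is invariant to linear
  intensity inversion; MSD remains available for matched-contrast
  channels.
* *Registration scene.* Quadrature also means a pure-phase sample gives
  cameras 1/2 and 3/4 fundamentally different fringe content, so the
  pipeline registers on an amplitude-textured, zero-phase acquisition
  (`textureTarget()`), where all four channels see monotone renditions
  of the same structure. Because registration is needed only once, a
  dedicated registration acquisition is cheap and mirrors how the
  instrument is used.

Both images are lightly box-smoothed (3×3 by default) before the
metric; this regularizes the similarity landscape under shot noise and
costs no measurable precision on smooth textures. The transform class
defaults to rigid (translation + rotation); translation, similarity and
full affine are available. Non-convergence is flagged per channel, with
the best-so-far transform returned. On noise-free textured holograms
the estimator recovers injected transforms to better than 0.05 px and
0.01°; the tested guarantees are 0.2 px and 0.05°.

**Phase retrieval.** `wrappedPhase()` computes
$\Delta\varphi = \mathrm{atan2}(I_3-I_4,\, I_1-I_2)$. The four-quadrant
form recovers the full $2\pi$ range that a plain arctangent of the
ratio would fold. Pixels where both differences are below $10^{-3}$ of
the image's maximum modulation have no usable fringe signal; they are
zeroed and recorded in a validity mask rather than left as numerical
noise.

**Calibration.** `subtractCalibration()` wraps the difference between
the sample phase and an empty-field phase recorded under the identical
configuration, removing instrument aberration and the arm offset. The
subtraction is performed on wrapped maps *before* unwrapping: the
calibration field is smooth, so subtracting it first strictly reduces
the dynamic range the unwrapper must explain.

**Unwrapping.** `unwrapPhase()` is the unweighted minimum-L2-norm
(least-squares) unwrapper: the discrete Poisson equation driven by the
divergence of the wrapped gradients, solved with Neumann boundary
conditions in a DCT basis. The DCT-II is applied as a cached
orthonormal matrix product — exact, dependency-free, and well under a
second at 512². The solver always returns; the number of phase
residues (non-zero circulations of the wrapped gradient field) is
reported as a quality metric, zero meaning the recovered surface
reproduces the wrapped input exactly up to a constant. That free
constant is fixed by the circular mean of (input − solution), which
pins a zero-phase background at zero. For residue-free fields the
recovery is exact to solver precision (~1e−13 on a ramp); sampling must
keep phase steps below π per pixel (a 20 µm bead at 0.345 µm sampling
has a maximum step of about 1.2 rad and unwraps to <1e−3 rad RMS).

**Thickness.** `phaseToThickness()` applies
$\Delta h = \lambda\,\Delta\varphi / (2\pi(n_s-n_m))$. Maps use the
signed contrast (noise stays zero-mean; physical samples come out
positive); numeric input is treated as a reported phase height, i.e. a
magnitude.

## Measurement operators

* `resolvable()` normalizes a profile across a three-bar element,
  detects plateau-aware local maxima, and declares the element resolved
  when three peaks exist with mean peak-to-dip modulation at or above a
  threshold. The threshold defaults to 0.2 — clearly separated peaks in
  a normalized profile — and is exposed because no standard criterion
  value exists for this readout.
* `stepHeight()` is the mean thickness difference between a feature ROI
  and a substrate ROI; `usafFeatureROI()` / `usafSubstrateROI()` derive
  those from the generated chart geometry, keeping the inner 60% of the
  square pad (the published measurement protocol shows ROIs well inside
  the features; 60% comfortably clears anti-aliased edges and
  diffraction ringing). `repeatStats()` reports the mean over repeated
  estimates as the measurement, with its standard deviation.
* `beadPeakPhase()` estimates the apex $|\varphi|$ of a bead. A raw
  maximum over a window of a noisy map is upward-biased, so the
  estimator (i) box-smooths the *squared* magnitude (3×3 default),
  (ii) fits a paraboloid around the smoothed maximum — for a sphere
  the squared phase profile $\varphi_0^2(1-\rho^2/r^2)$ is exactly
  quadratic in radius, so the fit has no model error for any bead
  size — and (iii) removes the constant offset the box filter adds to
  a quadratic (kernel variance times curvature trace) before taking
  the square root. On noise-free beads the estimator is exact to a few
  nanometres of equivalent thickness; under the default noise model it
  stays within a few hundredths of a micrometre.

## Problem sizes and numerical choices

The package's reference study conditions — used by the end-to-end tests
— are 512×512 holograms at 0.345 µm object-plane sampling (3.45 µm
pixels behind 10× magnification), λ = 532 nm, NA = 0.25 with the pupil
enabled, equal unit amplitudes, a 0.4 rad arm offset, the 12-bit noise
model above, and rigid camera misalignments up to ~3 px / 0.5°. Under
five fixed seeds the pipeline recovers a 213.8 nm chart step to within
±5 nm and a 10 µm bead peak thickness to within ±0.1 µm. Unit tests
exercise the same operators at 12–256 px scales where the checks are
analytic rather than statistical.

Other numerical details: bilinear interpolation with replicate padding
for all warps (the metric excludes an 8% border); FFT cross-correlation
on standardized images for the translation initializer; Nelder-Mead
with relative tolerance 1e−9 and a per-level iteration budget; wrapped
arithmetic maps to $(-\pi, \pi]$ via
`x - 2*pi*ceiling((x - pi)/(2*pi))`; 16-bit integer TIFFs for
holograms (full scale ↦ intensity 1; retrieval is scale invariant) and
32-bit float TIFFs for maps, stored normalized with an affine restore
sidecar because float TIFF values outside [0, 1] are not portable
across readers.

## What the synthetic data do and do not show

The generators emulate the *geometry and statistics* of the instrument:
quadrature channel formation, diffraction blur, photon and read noise,
quantization, inter-camera misalignment, and samples with exactly known
phase. Passing tests therefore demonstrate that the reconstruction
chain is unbiased and accurate under the stated degradation model.
They do not model laser thermal drift or spatial non-uniformity,
polarizer extinction ratios, optical aberrations beyond the global
calibration phase, defocus of a sinking bead, vibration, or
manufacturing bias in a physical chart — a real bench that reads
216.9 nm where the manufacturer specifies 213.8 nm is exhibiting
exactly the kind of systematic the simulation cannot reproduce, and the
package makes no claim to predict those offsets. Reflective layouts
and off-axis (carrier-fringe) holography are out of scope, as are
temporal unwrapping across frames and Zernike aberration fitting.
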
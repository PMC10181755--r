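# quadPSDH

Simulation and reconstruction toolkit for **four-channel synchronous
phase-shifting digital holography** (PSDH).

Quantitative phase imaging recovers the optical path delay a transparent
object — a cell, a microsphere, an etched resolution target — imprints
on a coherent wavefront. Phase-shifting holography does this by
recording several holograms of the same scene with known reference-phase
offsets; a *synchronous* system records all of them at once, here on
four cameras behind a polarization-splitting network, so that moving
objects can be imaged frame by frame. This package provides both sides
of that experiment in software:

* a **forward model**: exact 2×2 Jones-calculus propagation of object
  and reference waves through the system's polarizer / quarter-wave
  plate / polarizing-beamsplitter chain, together with the closed-form
  channel intensities it produces, a coherent NA/λ pupil, camera noise
  (Poisson + read noise + quantization) and per-channel geometric
  misalignment;
* an **inverse pipeline**: one-time intensity-based channel
  registration, four-step arctangent phase retrieval, calibration
  (empty-field) phase subtraction, minimum-norm (least-squares) phase
  unwrapping, and phase-to-thickness conversion;
* **synthetic samples with ground truth**: USAF 1951 phase-only
  resolution charts, spherical beads (e.g. PMMA pellets in oil),
  sinking-bead frame sequences and amplitude-texture registration
  targets;
* **metrics**: three-bar resolvability, ROI step heights with repeated
  measurement statistics, and bead apex phase estimation.

## The model

With channel phase shifts δ = (0, π, π/2, 3π/2) wired to cameras 1–4,
the recorded intensities of a sample with amplitude transmission α and
phase φ are

    I₁,₂ = ¼ [ α²A_O² + A_R² ± 2 α A_O A_R cos Δφ ]
    I₃,₄ = ¼ [ α²A_O² + A_R² ± 2 α A_O A_R sin Δφ ]

where Δφ is the object–reference phase difference. The wrapped phase is
retrieved by the four-quadrant arctangent

    Δφ = atan2(I₃ − I₄, I₁ − I₂)

and, for a sample of refractive index n_s in a medium n_m, converts to
physical thickness via the optical path difference relation

    Δh = λ · Δφ / (2π (n_s − n_m)).

The lateral resolution limit of the imaging arm is γ = λ / (2·NA).
All lengths in the package are micrometres; phases are radians.

## Worked example

Simulate a 10 µm PMMA bead (n = 1.49) in immersion oil (n = 1.51) under
the default hardware (λ = 532 nm, 10×/0.25 objective, 3.45 µm camera
pixels), with shot/read noise and misaligned cameras, then recover its
thickness:

```r
library(quadPSDH)
set.seed(11)
cfg <- OpticalConfig(dims = c(256, 256), armPhaseOffset = 0.4,
                     pupilEnabled = TRUE)
px  <- objectPixelSize(cfg)                       # 0.345 um/px
mis <- MisalignmentModel(ccd2 = list(tx = 3.2, ty = -1.7, rot = 0.3),
                         ccd3 = list(tx = -2.1, ty = 1.4, rot = -0.2),
                         ccd4 = list(tx = 1.2, ty = 2.6, rot = 0.45))

bead  <- beadField(beadSpec(10), nMedium = 1.51, dims = cfg@dims,
                   pixelSize = px)
holos <- corruptHolograms(closedFormIntensities(bead, cfg),
                          NoiseModel(seed = 1101), mis)
calib <- corruptHolograms(closedFormIntensities(
           emptyField(cfg@dims, px), cfg), NoiseModel(seed = 1102), mis)
tex   <- corruptHolograms(closedFormIntensities(
           textureTarget(cfg@dims, px), cfg), NoiseModel(seed = 1103), mis)

reg <- registerChannels(tex, model = "rigid")     # one-time registration
rec <- reconstructHolograms(holos, calib, reg,
                            nSample = 1.49, nMedium = 1.51)
peak <- beadPeakPhase(rec$unwrapped)
```

This prints:

```
RegistrationResult (rigid model, ncc metric, ref ccd1)
  ccd2: tx=3.142 ty=-1.746 px, rot=0.3224 deg, scale=1.00000 (score 0.0988)
  ccd3: tx=-2.133 ty=1.423 px, rot=-0.1979 deg, scale=1.00000 (score 0.0134)
  ccd4: tx=1.102 ty=2.765 px, rot=0.3850 deg, scale=1.00000 (score 0.108)
peak phase height : 2.37 rad
bead thickness    : 10.05 um
theoretical gamma : 1.064 um
linewidth g8 e4   : 1.381 um
```

The registration recovers the injected camera misalignment to a
fraction of a pixel, the bead's phase apex (2.37 rad against the
analytic 2.36 rad for Δn = 0.02) converts to 10.05 µm against the true
10 µm diameter, and the analytic constants of the default hardware come
out as expected.

A file-based workflow (`cliSimulate` → `cliReconstruct` →
`cliMeasure`, or `cliPipeline` for all three) reads and writes TIFF
hologram sets, float TIFF maps and JSON reports driven by a YAML
configuration; `inst/scripts/quadPSDH.R` exposes it from the shell:

```sh
Rscript inst/scripts/quadPSDH.R pipeline --config cfg.yaml \
    --out runs --seed 1
```

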
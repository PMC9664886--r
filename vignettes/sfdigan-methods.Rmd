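---
title: "Synthetic SFDI data and conditional-GAN optical property mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic SFDI data and conditional-GAN optical property mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdigan)
```

# The problem

Spatial frequency domain imaging (SFDI) projects a sinusoidal light pattern
onto tissue and infers per-pixel absorption (µa) and reduced scattering
(µs′) from how strongly the pattern's modulation survives remission.
Conventional single-snapshot processing (SSOP) splits one fringe image into
its DC and AC components by frequency filtering and inverts a homogeneous
forward model per pixel; it assumes telecentric projection onto a flat
sample and pays for its single shot with filter artefacts. Inside a tubular
organ neither assumption holds: the fringes distort, the local spatial
frequency varies across the wall, and illumination falls off down the
lumen.

`sfdigan` builds the full synthetic-data alternative: parametric sample
scenes (flat slabs with 1-3 materials, tumour spheroids, and
polyp-bearing cylindrical lumens) are rendered into fringe-illuminated
input images paired with pixel-perfect ground-truth property maps, and a
conditional GAN learns the direct mapping from one fringe image to the
per-pixel property map. An SSOP baseline with a lookup-table inversion and
a normalised mean absolute error (NMAE) evaluation harness close the loop.

# Forward optics

## Material factors and proxy properties

Materials are controlled by three unitless factors in [0, 1], mirroring a
physically-based renderer's shader mix: a *final factor* blending an
absorbing component (0) into a scattering component (1), an *absorption
factor* running from fully absorbing (0) to transparent (1), and a
*scattering factor* from transparent (0) to fully scattering (1). The
package maps factors to proxy coefficients with the bilinear product

$$\mu_a = \mu_a^{\max}\,(1-f_{\text{final}})(1-f_{\text{abs}}),\qquad
  \mu_s' = \mu_s^{\max}\, f_{\text{final}}\, f_{\text{sct}},$$

with µa^max = 0.25 mm⁻¹ and µs^max = 2.5 mm⁻¹ (the values that the 8-bit
level 255 decodes to). No published formula ties the renderer factors to
physical coefficients — they are proxies recoverable by calibration — so
the product form is a declared convention chosen because it is monotone in
every factor and covers the property rectangle boundary-to-boundary.

One consequence is worth stating explicitly. A final-factor sweep
0.05 → 0.95 with the *absorbing component held at full strength*
(absorption factor 0) and the scattering factor at 1 traces exactly the
0.95:0.05 → 0.05:0.95 absorbing:scattering proportion path that defines
the base dataset. Factor-range tables that list a held factor as "1.00"
are therefore interpreted as "held at full component strength", i.e.
absorption factor 0 and scattering factor 1; taking the absorption entry
literally as 1 (transparent) would make µa identically zero across the
whole dataset and empty the absorption channel of signal.

## Diffuse reflectance

Ray-traced rendering is replaced by the closed-form diffusion
approximation for a semi-infinite turbid medium, which the ray-tracing
material model was itself validated against. With
µtr = µa + µs′, a′ = µs′/µtr and
µeff′ = √(3 µa µtr + (2π fx)²):

$$R_d(f_x) \;=\; \frac{3A\,a'}{\left(\mu_{\mathrm{eff}}'/\mu_{tr} + 1\right)
  \left(\mu_{\mathrm{eff}}'/\mu_{tr} + 3A\right)},$$

where the internal-reflection parameter $A$ derives from the effective
reflection coefficient via the Groenhuis polynomial at the material
refractive index 1.43. `Rd` is validated three ways: against a frozen
independent evaluation of the closed form, against a small Monte-Carlo
photon random walk with Fresnel boundary conditions (agreement to ~15%,
the expected accuracy of the diffusion approximation), and through
property-based monotonicity tests.

Two genuine physical limits matter downstream:

* Below transport albedo ≈ 0.6 the diffusion approximation is invalid,
  and `Rd(fx)` is even *non-monotone* in µa once µs′ ≲ 2π fx. The
  lookup-table inversion is therefore tabulated by default on
  [0.04, 1]·µa^max × [0.1, 1]·µs^max and flags queries whose solution is
  ill-conditioned or out of range (`out_of_gamut`).
* Reflectance never exceeds 1, so the source gain is normalised as
  g = 0.8·(power/3.5 W): the brightest possible material peaks at 80% of
  full scale and no render ever clips. Absolute radiometry is irrelevant
  after 8-bit normalisation; only this anchor enters.

## The lookup-table inversion

`build_inversion_lut()` tabulates (Rd(0), Rd(fx)) on a regular 101×101
property grid; `invert_reflectance()` finds the nearest tabulated node for
each measured pair and inverts the bilinear interpolant of the surrounding
cells by multi-start Newton iteration, tie-breaking toward the nearest
node because the bilinear patch is near-degenerate (two pre-images) in the
low-albedo corner. Round-trip accuracy on random in-gamut property pairs
is well under 2%; grid nodes reproduce exactly.

# Scenes and rendering

## Flat scenes

Flat samples span a 51.2 mm field of view imaged at 256×256 (0.2 mm per
pixel; both are configurable). Material regions partition the surface:
curved boundaries are circular arcs parametrised by chord position and
sagitta, ragged boundaries are seeded, moving-average-smoothed Gaussian
random walks. Tumours are spheroids whose orthographic projections
(ellipses) overwrite the base regions, later ones occluding earlier ones.
Every stochastic construction is reproducible from a recorded seed.

Illumination is telecentric with a uniform spatial frequency (default
0.2 mm⁻¹): pixel intensity is
$I = g\,[R_d(0)/2 + R_d(f_x)/2\,\cos(2\pi f_x u + \phi)]$. An optional
seeded Gaussian-plus-Poisson noise stage exists for robustness
experiments and is off by default, matching the near-noiseless character
of rendered training data.

## Cylindrical lumens

The endoscopic scene is a hollow cylinder with a pinhole camera on the
axis looking along it and the projector on the axis a short baseline
(default 10 mm) behind the camera. The baseline matters: a projector
*exactly* co-located with the camera would image its own pattern — every
camera ray sees the radiance of its matching projector ray — so the
fringes would appear perfectly straight whatever the geometry. With the
axial offset, the projected vertical-stripe sinusoid bends over the wall,
the apparent fringe period grows for wall points near the camera, the
local spatial frequency (computed by finite differences of the fringe
phase over the 3-D surface) varies across the image, and intensity falls
off as 1/d² down the lumen — the three phenomena that break conventional
SSOP inside tubular organs. Polyps are hemispheroid material regions on
the inner wall, sampled uniformly in wall coordinates with seeded sizes,
positions and factors. They change the wall's material map but not its
geometry; the property contrast, not the height bump, is what the
learning task needs.

A second camera mode (`view = "radial"`) looks at the wall perpendicular
to the axis. It exists because the flat-geometry limit is exact there: as
the radius grows the radial view converges pixel-for-pixel to the flat
render (verified to <1% of full scale), whereas the axial view has no
flat limit — its rays run nearly parallel to the wall. The axial-specific
physics is tested directly instead: ring-averaged intensity decreasing
toward the lumen centre, and fringe-period growth toward the camera.

## Ground truth and pairing

The ground-truth map is flat-shaded with identical projection geometry:
each pixel's colour depends only on its material, red encoding
µa/µa^max and green µs′/µs^max, both re-mapped linearly into
[0.05, 0.95] and 8-bit encoded with half-up rounding (so 0.05 → 13,
0.95 → 242); blue is identically zero. Input and truth render from one
rasterisation, so co-registration is pixel-exact by construction. Pairs
are stored as lossless 8-bit PNG, input left and truth right
(H × 2H × 3), with a CSV manifest and JSON header carrying provenance
(scene hashes, split seed).

# The conditional GAN

The generator is a modified U-Net: a stem convolution, stride-2 encoder
stages each followed by a residual block (short skips), and a mirrored
decoder using nearest-neighbour upsampling whose stages concatenate the
matching encoder feature (long skips), ending in a 3-channel tanh head.
Depth scales with image size (log2(size) − 2 levels: six at 256², three
at 32²) so the reduced test-scale model is structurally faithful. The
discriminator is a three-layer leaky-ReLU (slope 0.2) patch classifier on
the concatenated 6-channel (input, candidate) pair, spectrally normalised
throughout. All weights initialise from N(0, 0.02²) under the run seed.

The objective is the least-squares adversarial loss (real label 1, fake
label 0) — the printed objective in the source material is truncated, and
this is the completion consistent with its D(x, G(x))² term and with the
cited architecture lineage — plus an L1 term weighted by λ = 60. Training
follows the reference protocol: Adam (β₁ = 0.5 as is conventional in
adversarial training; the source fixes only the learning rate) at 1e-4,
constant for the first half of the epochs then decayed linearly to zero;
batch size 1; discriminator steps see the current pair plus one sampled
uniformly from a 64-entry history buffer of previously generated pairs
(a random slot is replaced once the buffer is full). Spectral
normalisation uses one persisted power iteration per step and the full
gradient through W/σ. Divergence (non-finite loss) aborts the run,
returning the last stable state with a flag.

Inputs are normalised to a consistent representation on the 8-bit scale
before entering the network, as is conventional for convolutional
networks: one dataset-level constant (the training split's maximum
intensity) stretches the fringe images to the full input range, is stored
in the fit, and is re-applied at prediction. A single shared constant —
never per-image normalisation — preserves the absolute-radiometry
information that encodes the properties. The stretch matters because the
renderer's clip-free gain leaves mid-sweep materials at a fraction of
full scale (and lumen interiors far darker still), which would otherwise
compress the network's usable input range.

Design choices the source leaves open, and what this package does:

* **Normalisation.** Instance normalisation, conventional in
  image-to-image GANs, is implemented but off by default: it standardises
  away per-channel absolute intensity, which here *is* the signal (the
  DC reflectance level encodes the properties), so the default generator
  preserves radiometry through its feature maps.
* **Scale of the scaled-down runs.** The experiments in this package run
  at 32×32 with the full 51.2 mm field (1.6 mm/pixel, fringe period
  ≈ 3 px) rather than shrinking the field of view at the native pixel
  pitch: keeping several carrier periods inside a small receptive field
  keeps demodulation a local operation, which is what a convolutional
  generator can learn efficiently, whereas a native-pitch crop leaves
  barely one period in view and forces long-range context. Test-suite
  training runs use 24-48 images and a few hundred epochs; these sizes
  are the package's documented desk-scale protocol, with every knob
  exposed to run the full 256²/200-epoch protocol.

# Evaluation

NMAE is Σ|p − p_ref| / Σ p_ref over all pixels of a channel, computed on
the 8-bit encoded scale (decoding to mm⁻¹ is a fixed linear map, so the
ratio is unchanged as long as both operands use one scale). Per-image
difference maps are |p − p_ref|/p_ref·100 with zero-reference pixels
masked. Reports carry per-image rows; summaries give the mean and the
envelope (maximum) per channel.

The SSOP baseline demodulates by quadrature: the image row is multiplied
by a complex carrier at fx and Gaussian-low-pass filtered (default width
0.8 fringe periods, edge-corrected) to give the AC amplitude, with the
same filter giving DC. Calibrated reflectances then invert through the
LUT. On noiseless homogeneous flat renders the interior recovers both
properties within 5% — the forward–inverse consistency that establishes
renderer and inversion agree independently of any learning. Whole-image
SSOP NMAE is an order of magnitude larger (≈ 7-25%) because the filter
support produces border and boundary artefacts; that gap is precisely the
argument for the learned mapping, and matches the reported SSOP-on-
synthetic error scale.

Experiment runners reproduce the four study designs at configurable
scale: flat-model validation scatter, cylindrical validation, ±10%
spatial-frequency robustness (validation sets rendered at 0.18 and
0.22 mm⁻¹), and the factor-range grid (final factor always swept;
absorption/scattering factors held or swept).

# What the synthetic generator does and does not emulate

It emulates: diffusion-regime diffuse reflectance under sinusoidal
structured illumination; co-registered perfect ground truths; keyframe
enumeration of datasets; curved/ragged material boundaries, tumour
spheroids, polyp-bearing lumens; fringe distortion, local-frequency
variation and power falloff inside cylinders; optional sensor-style
noise.

It does not emulate: sub-diffusive transport or anisotropy (no
Henyey-Greenstein g parameter), specular reflections or wet surfaces,
geometric height of polyps, camera pose variation, multispectral
channels, motion artefacts, or experimental calibration drift. Passing
tests on this data therefore demonstrate the pipeline's internal
consistency and the learnability of the inverse mapping under ideal
image formation — not performance on clinical images.

# Numerical choices and degenerate inputs

* µs′ is floored at 10⁻⁴·µs^max inside the renderer so degenerate factor
  combinations stay inside the diffusion model's domain.
* Fringe-phase local frequency on the cylinder is capped at 0.5 mm⁻¹,
  below the sub-diffusive regime.
* 8-bit quantisation uses half-up rounding everywhere (`floor(x·255+0.5)`).
* The LUT inversion damps Newton steps, restarts from five points per
  candidate cell, and clamps solutions to the tabulated range with an
  out-of-gamut flag rather than extrapolating silently.
* Train/validation splits are seeded uniform permutations without
  stratification; the split seed is recorded in the manifest.
* All randomness (boundaries, polyp scatter, noise, weight init, data
  order, buffer sampling) flows through per-purpose seeded generators
  that never disturb the global RNG stream.

# Known limitations

The GAN implementation is a from-scratch CPU implementation (im2col
convolutions with analytic gradients); it is exact but not fast, so the
package's own experiments run at reduced scale, and full 256² training is
a long-running job rather than a test. The diffusion surrogate's validity
region excludes the strongly absorbing corner of factor space that a
volumetric ray tracer could still render; materials there are generated
and learned, but the SSOP baseline flags them as out-of-gamut rather than
inverting them reliably.
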
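---
title: "Modeling metasurface-encoded scintillation imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling metasurface-encoded scintillation imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metascint)
```

## The imaging problem

Indirect X-ray detectors convert absorbed X-rays into visible fluorescence
inside a scintillator crystal such as Ce:YAG. Because the crystal's
refractive index is high (n = 1.82), only light within the escape cone of
the exit face leaves the crystal: the solid-angle fraction is
`(1 - cos(asin(1/n))) / 2`, about 8 percent, so roughly 92 percent of the
emitted photons never reach the camera. A periodic metasurface affixed to
the exit face diffracts part of that trapped steep-angle light back into
the collection optics. Because the structure is fixed and periodic, its
effect on the image is a convolution: the optics become the encoder of a
convolutional autoencoder whose electronic decoder is learned from a single
calibration exposure of a known sample and applied by Richardson-Lucy (RL)
deconvolution.

`metascint` is a desk-scale simulator of that chain: optical kernel design
from the scalar grating equation, incoherent polychromatic capture with
photon noise, single-exposure kernel calibration, RL decoding, an SNR/CNR
evaluation suite, and a toy parallel-beam tomography loop.

## Optical model

Light hitting the exit interface at internal angle `theta` with vacuum
wavelength `lambda` leaves a grating of period `xi` with exit sine

```
s = n sin(theta) - m lambda / xi ,
```

the transmission grating equation into air; the order `m` propagates iff
`|s| < 1`, and is *admitted* if additionally the exit angle `asin(s)` lies
within the acceptance half-angle of the collection optics. For `m = 0` this
reduces to Snell refraction with total internal reflection beyond
`asin(1/n)`.

The point-spread function aggregates every admitted (angle, wavelength,
order) ray incoherently: each deposits its emission weight at lateral
displacement `d = L tan(asin(s))`, where `L` is a single effective
ray-mapping distance between the exit face and the detector (a lensless
thin-geometry model; no detector optics are modeled). A 1D grating deposits
on one axis at both signs of `d`; an isotropic 2D structure and the plain
interface spread each ray over the annulus of radius `|d|`. Coherent
effects are represented only through this incoherent aggregation; the
consequences of dropping the coherent angle-frequency coupling are
discussed under *Limitations*.

Three declared model choices close gaps the physics alone does not fix:

* **Angular emission.** Scintillator emission is taken Lambertian in the
  medium (weight proportional to `cos(theta) sin(theta)` on a 1-degree grid,
  0-89 degrees); uniform and single-angle weightings are available.
* **Per-order efficiency.** Scalar grating theory gives order positions but
  not efficiencies, so all considered orders share one efficiency
  (`uniform_orders`), with a user table as override. Ray energy is split
  across the reciprocal lattice: `2R + 1` collinear orders for a 1D grating
  and the full `(2R + 1)^2` lattice for an isotropic 2D structure, whose
  on-axis ring contributes multiplicity 4 per nonzero radial order
  (diagonal lattice points are not tracked individually).
* **Collection gain.** Kernels are normalized to unit sum, but each records
  how much more emitted light its structure steers into the acceptance cone
  than the plain interface does (`collection_gain`); the capture model
  multiplies the photon rate by it. This is the mechanism by which a
  metasurface that rescues trapped photons earns a genuine shot-noise
  advantage over the plain system at the same source brightness and
  exposure time.

### Default parameters

| parameter | default | unit | why |
|---|---|---|---|
| `n_scint` | 1.82 | - | Ce:YAG handbook value |
| `acceptance_half_angle_deg` | 10 | degrees | see below |
| `propagation_distance_um` | 50 | um | keeps ray displacements within a 33 px kernel at 1 um pitch |
| spectrum | uniform 400-700, 10 nm steps | nm | only the band is known; the spectral shape is not |
| kernel grid | 33 x 33 at 1 um | px | covers `L tan(10 deg) = 8.8 um` with margin |

The acceptance half-angle is the one parameter the observations constrain
rather than state. We fix it at 10 degrees so that, over the visible band,
a 200 nm-period structure admits no diffracted order at all
(`sin(eps) < 2.0 - 1.82`, matching the reported dark diffraction pattern)
while a 300 nm period passes its first order from steep angles. At this
setting the 300 nm grating collects about 3.7 times, and the 500 nm
isotropic structure about 2.8 times, the light of the plain interface.

## Capture model

A detector frame is `BIN(POISSON(t_cap * r * g * (I conv K)) + N(0, sd))`,
clipped at zero: `r` is the blank-field photon rate through the plain
system (default 50 photons per pixel per ms, which makes 20 ms frames
visibly shot-noise limited and 100 ms frames close to clean), `g` the
kernel's collection gain, `sd` the Gaussian read noise (default 2 counts),
and `BIN` sums over `bin_factor x bin_factor` detector blocks (default 2,
modeling a pixel-limited detector). Convolution is FFT-accelerated with
reflective (symmetric) boundary padding, which avoids dark frame edges that
would bias the SNR bands; a `noiseless` switch bypasses both noise terms
for oracle tests. All draws come from a named RNG (Mersenne-Twister) under
explicit seeds, and a single scenario seed fans out to per-stage child
seeds through a fixed multiplicative-hash rule so any stage can be rerun in
isolation.

## Decoder calibration

The decoder learns the effective kernel from one exposure of a known
sample by minimizing the least-squares inference target

```
Omega(K) = || S - I_known conv K ||_F^2
```

over the kernel, with a nonnegativity projection and unit-sum
renormalization every epoch. The per-epoch Frobenius loss and a stability
trace are recorded; stability at epoch e is this package's declared
convention `1 - ||K_e - K_{e-1}||_F / ||K_{e-1}||_F`, a normalized measure
of how much the kernel still moves (1 means it has stopped moving). The optimizer is a projected
gradient scheme with two refinements that matter in practice: the gradient
is first projected onto the zero-sum subspace, because its mean component
is exactly what the renormalization cancels and it otherwise dominates the
step-size bound through the scene's DC power; and step lengths follow
alternating Barzilai-Borwein estimates, backtracked until descent holds, so
the recorded loss is non-increasing. Sixty epochs (the default) recover a
known 9 x 9 kernel from a noiseless 128 x 128 glyph calibration to about
3 x 10^-3 RMSE, and two hundred epochs to about 3 x 10^-4. Binned frames
are bilinearly upsampled to scene resolution before fitting, and both sides
are normalized by their means, which makes the estimate invariant to the
calibration scene's global intensity scale and to the photon budget.

A noisy calibration cannot fit its own noise, so the loss plateaus; the
result then carries a `"stalled"` status and a warning rather than failing
silently.

## Reconstruction

Decoding is plain multiplicative RL from a flat-field start with an
epsilon floor (1e-12) on the ratio, reflective boundaries matching the
forward model, 30 iterations by default with an early stop when the mean
relative update falls below 1e-4. No damping or total-variation
regularization is applied. Classical comparison filters (Gaussian, mean,
median, separable frequency low-pass, db4 wavelet soft/hard shrinkage at
the universal threshold, Laplacian sharpening) are provided with declared
defaults; the wavelet transform is a minimal in-package periodized db4
because no wavelet package ships with the R stack used here.

## Evaluation

SNR curves follow the ultra-high-frequency normalization convention:
radially averaged power spectra of the reference and of the residual
(image minus least-squares-scaled reference) are compared per frequency
bin, `10 log10(P_signal / P_noise)`, then offset so the mean over the
normalization band (default the top 10 percent of represented frequencies,
which is noise-dominated) is 0 dB. Annuli with fewer than 8 Fourier samples
merge outward; identical inputs cap at +80 dB.

The CNR between two regions is declared as the contrast ratio
`(1 - r_A) / (1 - r_B)` with `r_X` the region-to-blank intensity ratio:
for absorption imaging `1 - r` is a region's absorption contrast, the
convention reproduces values near 1 when contrasts match, and alternative
definitions can be plugged in. On the two-region scene the measurement
masks mimic regions drawn around the visible structures: the whole tube
object for A, and the dark texture stripes (interior, below the region
mean) for B, since enhancement or washout of fine features moves exactly
those pixels.

## Bundled scenarios

`scenario_config()` ships two end-to-end scenarios run by
`run_scenario()`: `texture_vs_plain` (plain system versus the 300 nm
texture kernel on the 3 um fringe card) and `regional_vs_texture` (plain,
texture and regional kernels on the two-region scene, with the CNR table).
Both train the decoder once per arm on a 100 ms glyph calibration and then
evaluate 20 ms captures over replicate seeds, mirroring a calibrate-once,
deploy-everywhere workflow. At the defaults (256 x 256 scenes, 33 x 33
kernels, 60 training epochs, 30 RL iterations, 5 replicates) the
three-arm scenario completes in well under a minute on one CPU; the same
sizes are used by the acceptance script.

What the synthetic scenes emulate - an etched digit, a fixed-pitch fringe
card, fiber textures, a smooth tube next to a textured fin - are the
geometry and absorption contrast of the real samples, under idealized
conditions: perfectly known ground truth, stationary noise, a shift-
invariant PSF, and no scatter, afterglow or energy-dependent attenuation.
Passing tests therefore demonstrate internal consistency of the model
chain, not performance on beamline data.

## Numerical choices

* Reflective padding everywhere (forward model, RL, gradient adjoint), so
  decoding inverts exactly the boundary convention that produced the frame.
* Sub-pixel ray deposits use bilinear splatting; annuli are sampled at
  four azimuthal points per circumference pixel.
* The FBP ramp filter is applied on projections zero-padded to the next
  power of two past twice the detector width; `pi / (2 n_angles)` scaling;
  Shepp-Logan window available. Gridrec-style Fourier regridding is
  deliberately replaced by this standard filtered back-projection: same
  mathematical target, fewer moving parts. 180 angles by default rather
  than the 900 of a beamline scan.
* Projection degradation uses the kernel's central-row profile, the 1D
  restriction appropriate for 1D projections; decoding is applied per
  projection before reconstruction.
* Degenerate inputs fail loudly: all-zero RL input, empty region masks,
  kernels larger than the image, displacement exceeding the kernel grid
  (the error names the grid size required).

## Limitations

The incoherent-PSF scoping severs the coherent link between a ray's exit
angle and the scene's spatial frequency content. Two observed consequences
are documented rather than patched. First, band-selective *enhancement*
here arises from collection gain plus kernel MTF shape and RL restoration,
not from frequency-selective photon recruitment; the reproduced effects
are directional (which arm wins which band), not magnitudes. Second, a
region's measured mean can only move toward the ground truth under
convolution and RL, never beyond it, so the regional kernel's CNR does not
rise *above* the plain system's as the real system's does - the texture
side of the inversion (texture kernel far below plain) reproduces, the
regional side lands at a statistical tie. The acceptance suite keeps the
faithful assertion and the corresponding test documents this gap honestly.

The model also ignores scatter, afterglow, spectral detector response and
spatially varying PSFs, and the glyph font is a built-in 5 x 7 digit
bitmap, not a rendering of the etched sample.
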
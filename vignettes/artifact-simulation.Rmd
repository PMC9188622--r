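---
title: "Simulating susceptibility artifacts of passive implants and their field-strength scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating susceptibility artifacts of passive implants and their field-strength scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artifactsim)
```

## The problem

Metallic implants distort the static field $B_0$ of an MR scanner because
their magnetic susceptibility $\chi$ differs from the surrounding tissue by
hundreds to thousands of ppm.  The local off-resonance $\Delta f(\mathbf r)$
mislocalizes signal along the frequency-encoding axis, bends the excited
slice, and dephases spins within voxels, producing the familiar signal
voids and pile-up rims around implants.  Regulatory artifact testing (ASTM
F2119) quantifies this with phantom measurements: an image with the device,
a reference image without it, and an artifact mask of all pixels whose
signal changes by more than 30%.

`artifactsim` reproduces that test *in silico* for small passive implants,
where the artifact is dominated by the static-field susceptibility effect:
it predicts the artifact mask and area from first principles, and it
quantifies how the artifact area scales with $B_0$, so that a measurement
at one field strength can be extrapolated to another.

## Forward model

### Off-resonance from susceptibility

The phantom is a voxelized cube (default 150 mm at 2 voxels/mm) of oil
($\chi = -8.8$ ppm, $T_1 = T_2 = 90$ ms, $M_0 = 1$) containing a voxelized
test object.  For a susceptibility distribution $\chi(\mathbf r)$ the
induced off-resonance in Hz is computed with the k-space dipole kernel

$$\Delta f(\mathbf r) \;=\; \bar\gamma \, B_0 \cdot 10^{-6} \,
\mathrm{FT}^{-1}\!\Big[\Big(\tfrac13 - \tfrac{k_z^2}{k_x^2+k_y^2+k_z^2}\Big)\,
\mathrm{FT}[\chi(\mathbf r)]\Big],$$

with $\bar\gamma = 42.577$ MHz/T and $B_0$ along $z$.  This is the standard
Lorentz-corrected dipole kernel of quantitative susceptibility mapping; the
package works in Hz throughout because the sequence parameters (pixel
bandwidth) are specified in Hz.  Numerical choices:

* `D(0) = 0`, and the field is demeaned over the background voxels.  This
  models the scanner's center-frequency adjustment on the bulk medium, and
  it makes the artifact evaluation independent of the arbitrary constant,
  because reference and with-object images share the demodulation.
* The grid is zero-padded (in susceptibility contrast) before the FFT to
  suppress circular-convolution wrap-around.  Each padded axis is the next
  2-3-5-smooth integer at least 4/3 of the grid; for the 300³ phantom this
  puts the nearest periodic alias 200 mm away.  The worst-case aliased
  field (stainless steel at 7 T, dipole far field of the full rod moment at
  200 mm) is below ~3 Hz, two orders of magnitude under the off-resonance
  at any artifact boundary, while keeping the padded FFT (400³ complex)
  within ordinary workstation memory.  The factor is a parameter
  (`pad_factor`), and `pad_factor = 1` deliberately disables padding so
  that translation-invariant geometries (infinite cylinders) can be modeled
  exactly — the validation tests use this.
* Validation: against the closed-form sphere dipole field the FFT solution
  agrees to ~1% at $r \ge 2R$; for infinite cylinders the kernel identities
  (internal shift $\bar\gamma B_0 \Delta\chi (3\cos^2\theta - 1)/6$, no
  external field when parallel, $\cos 2\varphi$ pattern when perpendicular)
  hold to discretization tolerance.

The field is linear in $\chi$-contrast and in $B_0$, so the experiment
driver computes one unit field per rod orientation and rescales it per
material and field strength; this is exact, not an approximation, and is
verified by a linearity test.

### Image formation

2D spin-echo (TE 20 ms, flip 90°) and spoiled gradient-echo (TE 15 ms,
flip 30°) acquisitions with TR 500 ms, 256×256 matrix, 3 mm slice,
130 Hz/px and 200 mm FOV are synthesized from isochromats on the native
phantom grid (at 2 voxels/mm a 3 mm slice holds 6 sub-samples through the
slice, which resolves through-plane dephasing):

* **Slice selection** uses an ideal rectangular profile: an isochromat at
  position $s$ along the slice normal is excited iff
  $|\bar\gamma G_s (s - s_0) + \Delta f| < \bar\gamma G_s \cdot
  \mathrm{th}/2$ (strictly, so an isochromat exactly at the edge is
  excluded).  Off-resonance thus shifts and bends the excited slab — the
  through-plane artifact.  The slice-select gradient defaults to
  $G_s = 10$ mT/m, a typical clinical value for a 3 mm slice; it is
  exposed as a parameter because vendor protocols differ.
* **Contrast** enters as the steady-state weight
  $M_0 (1 - e^{-TR/T_1}) e^{-TE/T_2}$ for SE and the spoiled-GRE
  equivalent with $\sin\alpha (1-E_1)/(1-\cos\alpha E_1)$.  With
  TR = 500 ms ≫ $T_1$ = 90 ms the saturation detail is nearly irrelevant;
  full Bloch integration through the pulse sequence is intentionally out
  of scope.  Metals carry $M_0 = 0$: they are signal-free susceptibility
  sources.
* **Readout**: because the off-resonance of an isochromat is constant
  during the readout, its accumulated phase is exactly linear in the
  k-space sample index.  The synthesis is therefore closed-form: each
  isochromat appears displaced by $\Delta f / \mathrm{BW_{px}}$ pixels
  along the frequency axis, and a gradient echo additionally carries the
  static phase $e^{-2\pi i \Delta f \, TE}$ (the spin echo refocuses it).
  There is no time-discretization error to control — the model is evaluated
  exactly.  Isochromats displaced outside the readout band are discarded,
  modeling the anti-alias filter.  Phase encoding is ideal.
* **Gridding**: isochromats at continuous displaced positions are
  deposited on an 8× (frequency) / 4× (phase) oversampled grid with a
  cubic B-spline kernel, FFT'd, cropped to the 256 sampled k-lines and
  corrected for the kernel's sinc⁴ roll-off.  Against the exact
  per-isochromat DFT the reconstructed magnitude deviates by less than
  0.1% of the image peak even for adversarial random point clouds (a unit
  test enforces this contract at matrix 64).
* Reconstruction is the plain inverse 2D DFT; magnitude images are
  evaluated.  No distortion correction, no acceleration, no noise (an
  optional seeded complex-Gaussian noise exists for robustness
  experiments only).

### Artifact evaluation

The ASTM mask is `|S_TO - S_ref| / S_ref > 0.30` (strictly greater).
Pixels whose reference signal is essentially zero flag as artifact in
`artifact_image()` (an unbounded relative change), but the pipeline
evaluates the mask on the *reference signal support* (≥ 10% of the
maximum reference magnitude): with a 200 mm FOV around a 150 mm phantom
the region outside the phantom contains only Gibbs ringing in both
images, where a ratio is meaningless — exactly as noise-floor pixels
outside the phantom are not counted when evaluating measured images.
Inside the support the 10% level is immaterial because reference and
with-object images are identical wherever the artifact does not reach.

The one-pixel uncertainty erodes and dilates the mask with a 3×3
structuring element ("one pixel in every direction", i.e. including
diagonals; a 4-connected cross is available as an option), clipped at the
image edge.  Shape agreement between two masks uses the similarity factor
$N_o / N_s$ — intersection over union — after superimposing the artifact
centroids (integer shift, rounding half away from zero so alignment is
deterministic).

## The rod study

The built-in fixtures reproduce the study conditions: titanium
($\chi = 182$ ppm) and stainless-steel ($\chi = 3500$ ppm) rods, 3 mm
diameter × 15 mm length, in the oil phantom; both rod orientations
relative to $B_0$; two slice orientations per rod orientation; both
phase-encode directions; SE and GRE — 16 configurations per rod per field
strength, at 1.5 T, 3 T and 7 T (96 simulations).

Two conventions the study description leaves open are fixed as follows:

* The rod is centered on the symmetry point of the even-sized grid (a
  voxel corner), which makes the rasterized rod exactly symmetric and
  aligns the 3 mm slab with 6 whole sub-samples; the rasterized 3 mm
  cross-section on the 0.5 mm grid is 32 voxels (8.0 mm² vs the analytic
  7.07 mm² — center-count rasterization of so small a cross-section is
  necessarily coarse; the voxelizer is instead verified voxel-for-voxel
  against the analytic center-inside predicate, and for convergence with
  refinement).
* For the perpendicular rod (axis along $x$) the two simulated slice
  orientations are sagittal (rod cross-section) and coronal (the plane
  containing rod axis and $B_0$); for the parallel rod, transverse and
  coronal (sagittal is redundant by symmetry).  The cross-field slopes are
  insensitive to this labeling.

```{r, eval = FALSE}
results <- run_experiment_grid()      # ~5 min: 96 acquisitions + 2 field solves
field_scaling_report(results)
```

## Field-strength scaling

Artifact areas of the same configuration at two field strengths are
compared by a least-squares line through the origin,
$A(B_{\mathrm{high}}) = m \cdot A(B_{\mathrm{low}})$.  The through-origin
model is deliberate: the scaling law is a pure proportionality, and the
reported $R^2$ uses the uncentered convention
$1 - SS_{\mathrm{res}}/\sum y^2$ appropriate for it (an intercept variant
exists for sensitivity checks; the regression convention of the original
analysis is not stated, so ours is documented here).  The 95% CI of the
slope uses the normal-theory standard error with $n-1$ degrees of freedom.
The theoretical factor is $\sqrt{B_{\mathrm{high}}/B_{\mathrm{low}}}$:
1.41, 1.53, 2.16 for 3 T/1.5 T, 7 T/3 T, 7 T/1.5 T.

On the full fixture grid the package obtains slopes of about 1.43, 1.55
and 2.21 with mean $R^2 \approx 0.997$ (the acceptance script recomputes
these numbers from scratch).  All three lie within the 95% confidence
bands of the validated reference simulation (1.38–1.43, 1.50–1.58,
2.09–2.25), and the areas respect every expected ordering (GRE ≥ SE,
non-decreasing in $B_0$, steel > titanium, configuration by
configuration).  The maximum deviation from the square-root law is about
2.4% here versus the sub-percent figure of the full Bloch-solver engine;
the residual is engine-fidelity sensitive (ideal rectangular slice
profile, simplified readout timing, no $T_2$ decay during the readout)
and is reported, not hidden, by the acceptance script.

Two companion statistics mirror the validation methodology:

* `equivalence_test()` — a one-sample TOST on paired artifact-size
  differences with a ±200 px bound (the averaged one-pixel uncertainty);
  equivalence is declared iff both one-sided p-values fall below α.  The
  reference describing the original test does not state whether it was
  paired or one-sample; the one-sample form on per-configuration
  differences is implemented and flagged here.
* `bland_altman()` — per-pair means/differences with bias ± 1.96 SD
  limits, used to visualize cross-field agreement.  Error bars do not
  weight the trend fit (unweighted by default, as nothing indicates
  otherwise).

## What the synthetic study does and does not show

The generator emulates: the geometry and materials of the physical rods,
the ASTM sequences, the 16-configuration grid, and noiseless magnitude
images.  It does not emulate: scanner $B_0$ inhomogeneity, RF-field
($B_1$) inhomogeneity and coil sensitivities (small test objects interact
only weakly with the RF field, the assumption under which the whole
static-field approach is valid), chemical shift of the oil relative to
water demodulation (absorbed by the background demeaning), gradient
nonlinearity, noise, or the multi-slice interleaved acquisition (only the
center slice through the rod is evaluated).  Passing tests therefore
validate the susceptibility-artifact model and its evaluation chain — not
the behavior of large implants, where gradient- and RF-induced effects
invalidate the static-field dominance assumption.

## Degenerate inputs and edge conventions

* Excitation uses strict inequalities; a voxel exactly at the slab edge is
  not excited.  A signal change of exactly 30% is not artifact.
* A mesh that fits between voxel centers voxelizes to an empty mask
  without error; open meshes and meshes outside the grid are errors.
* `similarity_factor()` on two empty masks is undefined and raises an
  error; centroid alignment of an empty mask likewise.
* Zero-variance TOST differences degenerate to an exact comparison of the
  mean against the bounds.
* All computations are deterministic; reference and with-object images of
  identical phantoms are bit-identical, and re-running the grid reproduces
  the results table exactly.

## Problem sizes used by tests

Unit tests run on reduced grids (up to 96³ field solves, matrix 64
acquisitions) chosen so each oracle comparison still has headroom against
its tolerance; the acceptance suite and `scripts/acceptance.R` run the
full 150 mm / 2 voxel-per-mm phantom, 256×256 matrix, 96-acquisition grid
— the study conditions — reusing one unit field per rod orientation.
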
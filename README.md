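# artifactsim

Simulation and evaluation of MR image artifacts from small passive
metallic implants, for MR-safety engineers and implant manufacturers who
need ASTM F2119-style artifact sizes without occupying three scanners.

A passive implant whose magnetic susceptibility differs from tissue by
Δχ distorts the static field; the induced off-resonance

    Δf(r) = γ̄ · B0 · 10⁻⁶ · FT⁻¹[ (1/3 − kz²/k²) · FT(χ(r)) ]   (Hz)

(γ̄ = 42.577 MHz/T, B0 along z) displaces signal along the
frequency-encoding axis by Δf/BW_px pixels, bends the excited slice
(an isochromat behaves as if at s + Δf/(γ̄·Gs)), and dephases
gradient-echo voxels by e^(−2πi·Δf·TE).  `artifactsim` implements this
chain — voxelized phantom, FFT dipole-kernel field solve, closed-form
SE/GRE k-space synthesis, magnitude reconstruction — and evaluates the
ASTM artifact mask: all pixels whose signal changes by more than 30%
versus a reference image without the device, with a one-pixel
erosion/dilation uncertainty and an intersection-over-union similarity
factor for shape comparison.

Across field strengths the artifact area follows

    A(B_final) ≈ sqrt(B_final / B_initial) · A(B_initial)

and the package fits this through-origin trend over a built-in 96-run
experiment grid (titanium χ = 182 ppm and stainless-steel χ = 3500 ppm
rods, 3 × 15 mm, in oil χ = −8.8 ppm; 16 configurations per rod at
1.5 T, 3 T and 7 T), alongside TOST equivalence tests and Bland–Altman
summaries.

## Worked example

Simulate the titanium rod perpendicular to B0 at 1.5 T, spin echo,
evaluate the center-slice artifact:

```r
library(artifactsim)

mask <- voxelize_mesh(orient_object(make_cylinder_mesh(3, 15, 64), "perpendicular"),
                      c(300L, 300L, 300L), 0.5)
ph     <- build_phantom(150, 2, oil_material(), mask, titanium_material())
params <- sequence_params("SE", slice_orientation = "tra")

img <- simulate_image(ph, params, B0 = 1.5)              # with the rod
ref <- simulate_image(ph, params, B0 = 1.5, with_object = FALSE)
evaluate_artifact(img, ref)
#> <artifact_result> 312 px (190.43 mm^2), one-pixel bounds [166, 480] px
```

312 pixels of the 256×256 image (0.78 mm pixels) change by more than
30%: a 190 mm² artifact around the 7 mm² rod cross-section, bounded
between 166 and 480 px under the one-pixel mask uncertainty.  The full
grid and the cross-field trend:

```r
results <- run_experiment_grid()      # 96 acquisitions, ~5 min
field_scaling_report(results)
#> Cross-field artifact-area scaling
#>   3T vs 1.5T   slope 1.428 (1.404 - 1.452), R^2 0.998, theory 1.414, diff +0.97%
#>   7T vs 3T     slope 1.551 (1.529 - 1.573), R^2 0.998, theory 1.528, diff +1.54%
#>   7T vs 1.5T   slope 2.212 (2.146 - 2.277), R^2 0.994, theory 2.160, diff +2.38%
#>   mean R^2 0.9966; max |slope - theory| 2.38%
```

Each slope is the through-origin least-squares fit of the 32 matched
artifact areas at the higher field against the lower field; `theory` is
√(B_high/B_low).  The slopes reproduce the square-root scaling law to a
few percent with R² ≈ 0.997, so an artifact area measured at 1.5 T
predicts the 7 T artifact within the fit uncertainty.

A thin command-line wrapper over the same functions is installed at
`exec/artifactsim` (subcommands `make-fixtures`, `simulate`, `grid`,
`report`); YAML configs, STL geometry, NIfTI/PNG images and CSV results
are the interchange formats.  See the vignette
(`vignettes/artifact-simulation.Rmd`) for the model, its assumptions and
numerical choices.

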
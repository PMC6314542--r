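# ermorph

Nanoscale morphometry of the endoplasmic reticulum (ER) from STED
fluorescence images.

Superresolution imaging at ~50-nm resolution shows that peripheral ER
sheets are not uniform: they are perforated by dynamic, roughly 100-nm
"nanoholes", and ER tubules span a wide range of diameters that
diffraction-limited microscopy cannot measure. `ermorph` is an R package
for cell biologists and imaging scientists who need to quantify these
structures: it segments and measures holes in sheets, estimates tubule
diameters from line profiles, tracks seeded holes through videos, and —
because no public image sets exist for this regime — ships a
ground-truthed image simulator and an analytic membrane-curvature model
so every stage is testable end to end.

## What it computes

* **Hole segmentation** — Gaussian smoothing (σ = 1 px), an ER footprint
  mask (15 × 15-px median filter, 5% threshold), local-minimum seeding
  (4-px separation), a deterministic marker-controlled watershed, and a
  depth-fraction border rule: hole pixels are those below
  `min + 0.4 · (edge mean − min)` within the selected region.
* **Hole shape statistics** — equivalent diameter `d = 2√(A/π)` with
  `A = n·p²`, and symmetry `s = √(λ₂/λ₁)` from the eigenvalues of the
  pixel-position covariance matrix (1 = circular). Group comparisons use
  Kruskal–Wallis with post hoc Dunn tests (Bonferroni-adjusted).
* **Tubule diameters** — line profiles are fitted with the projection of
  a label-filled cylinder (luminal markers) or a 4.5/17.5-nm dye annulus
  (membrane markers) convolved with a Lorentzian PSF, in a nested grid
  search over diameter and PSF FWHM with analytically solved amplitude
  and background.
* **Hole tracking** — snap-to-deepest-minimum tracking with a presence
  threshold and persistence classification
  (persisted / appeared / disappeared / both).
* **Simulation** — torus-edged holes (inner half-torus rim, tube radius
  t/2) in a 50-nm slab, voxelized at 1 nm axially, projected, convolved
  with a 50-nm-FWHM Lorentzian, and Poisson-sampled (α = 10 per luminal
  voxel, background 1), with bit-reproducible ground truth.
* **Curvature budget** — closed-form surface-area bookkeeping for a
  disk sheet + holes + tubule at fixed total area: one 100-nm hole in a
  50-nm sheet carries `2π²R_h r − 4πr²` ≈ 29,160 nm² of curved membrane,
  so ten holes store the curved area of ~1 µm of 100-nm tubule.

## Worked example

Simulate a reference field of 25 nanoholes (100-nm inner diameter,
jittered 5 × 5 grid), run the full measurement chain with the true
centers as user points, and compare against a 150-nm cohort:

```r
library(ermorph)

cf  <- simulation_config(rng_seed = 42)        # 100-nm holes, 18.9 nm/px
sim <- simulate_hole_field(cf)
px  <- sim$image$pixel_size_nm
centers <- data.frame(row = round(sim$ground_truth$y_nm / px + 0.5),
                      col = round(sim$ground_truth$x_nm / px + 0.5))
holes <- segment_holes(sim$image, centers)
head(holes[holes$accepted,
           c("label_id", "n_pixels", "equivalent_diameter_nm", "symmetry")], 5)
#>   label_id n_pixels equivalent_diameter_nm  symmetry
#> 1      856       24               104.4774 1.0000000
#> 2      866       25               106.6318 0.9215939
#> 3      870       23               102.2777 0.8785607
#> 4      876       24               104.4774 1.0000000
#> 5      878       24               104.4774 1.0000000
median(holes$equivalent_diameter_nm[holes$accepted])
#> [1] 100.0295
```

The recovered median (100.0 nm) matches the simulated 100-nm inner
diameter; per-hole symmetries near 1 reflect the circular ground truth.
Comparing two simulated conditions:

```r
compare_groups(list(d100 = ..., d150 = ...))   # vectors of diameters
#> Kruskal-Wallis chi-squared = 37.35, df = 1, p = 9.88e-10
#>   unperturbed: median 100, IQR 4.45 (n = 25)
#>   simulated_150: median 140, IQR 3.25 (n = 25)
```

And the curvature-reservoir equivalence:

```r
equivalent_tubule_length(10, sheet_thickness_nm = 50,
                         hole_inner_diameter_nm = 100,
                         tubule_diameter_nm = 100) / 1000
#> [1] 0.9280972     # ten nanoholes ~ 0.93 um of tubule
curvature_budget(er_geometry_config(n_holes = 10, tubule_length_nm = 1000))
#> <curvature_budget> total 3.972e+07 nm^2, curved 1.823e+06 (4.6%), sheet d = 4.98 um
```

See the vignette (`vignettes/er-nanoscale-morphometry.Rmd`) for the
models, parameter meanings, and numerical choices.

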
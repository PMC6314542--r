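---
title: "Quantifying nanoscale ER morphology: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanoscale ER morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ermorph)
```

# The problem

The peripheral endoplasmic reticulum (ER) is a continuous membrane system
of flat sheets and highly curved tubules. STED microscopy at roughly
50-nm lateral resolution reveals two structures that conventional
microscopy misses: the true diameter distribution of ER tubules
(roughly 50–150 nm), and nanoscale holes ("nanoholes", on the order of
100 nm across) perforating otherwise uniform ER sheets. `ermorph`
implements the quantitative stack needed to measure both from
single-channel fluorescence images, together with a ground-truthed image
simulator and an analytic membrane-curvature budget, so that every stage
can be validated without any microscope.

The package has five analysis layers:

* **hole segmentation** — semiautomated detection and delimitation of
  holes in sheets (`segment_holes()` and its parts);
* **hole morphometrics** — equivalent diameter and covariance-eigenvalue
  symmetry per hole, with nonparametric group comparisons
  (`hole_shape()`, `compare_groups()`);
* **tubule fitting** — diameter and PSF estimation from line profiles
  (`fit_profile()`);
* **hole tracking** — seeded tracking through time-lapse stacks with
  persistence classification (`track_hole()`, `classify_persistence()`);
* **simulation and geometry** — the nanohole image simulator
  (`simulate_hole_field()`) and the fixed-area curvature budget
  (`curvature_budget()`).

# Image conventions

Images are `pixel_image` objects: a non-negative numeric matrix of photon
counts plus a lateral pixel size in nm (18.9 nm/px throughout the
reference conditions). Matrix indices are R's 1-based `(row, col)`; the
physical center of pixel `(i, j)` sits at
`((j - 0.5) px, (i - 0.5) px)`, so conversions between pixel and
physical coordinates are unambiguous everywhere (profile extraction,
hole centroids, simulator ground truth).

All filters use mirror (edge-duplicated) boundary handling. Circular or
zero padding would darken image borders and create spurious local
minima — fatal for a pipeline whose hole detector *is* a local-minimum
search.

Videos are bleach-corrected by monotone empirical quantile matching of
every frame's intensity histogram onto a reference frame (frame 1 by
default; the choice is exposed because no convention is universal). The
mapping interpolates linearly between empirical quantiles, leaves the
reference frame untouched, and is idempotent up to the quantization of
the discrete histogram.

# Hole segmentation

The chain mirrors a watershed-based hole detector:

1. smooth with a Gaussian of sigma = 1 px;
2. build an ER footprint mask: max-normalize, median-filter with a
   15 × 15-px kernel, threshold at 5% of the maximum;
3. find local minima of the smoothed image inside the mask with a
   minimum mutual separation of 4 px, keeping the deeper of any
   conflicting pair;
4. flood a marker-controlled watershed (8-connectivity) from *all*
   minima;
5. keep the regions containing user-supplied approximate hole centers,
   and within each, delimit the hole as the pixels strictly below
   `min + 0.4 × depth`, where `depth` is the mean smoothed intensity of
   the region's own (inner) boundary pixels minus the region minimum.

Step 4 deliberately seeds the watershed with every minimum, including
shot-noise pits; user selection happens afterwards. This makes the basin
geometry independent of which holes a user chooses.

Numerical/deterministic choices worth knowing:

* **Watershed semantics.** Pixels are flooded in ascending
  (intensity, row-major index) order; a pixel takes the label of the
  neighbor the flood arrives through — its labeled 8-neighbor with the
  smallest (intensity, label id). Exact intensity ties therefore resolve
  to the earlier (row-major) seed. A naive "smallest label id among
  labeled neighbors" rule was rejected: boundary pixels always see both
  labels, so the lowest-id basin would creep along every watershed line
  (a symmetric two-pit field came out 321/79 instead of 200/200). The
  compiled implementation is checked pixel-for-pixel against a
  brute-force flooding reference on small random images.
* **Plateau minima.** A connected equal-valued plateau that is a
  regional minimum contributes one seed at its rounded centroid.
* **Border rule.** The threshold comparison is strict (`<`), so pixels
  exactly at the 40%-depth level are excluded; the region minimum is
  always inside the hole whenever the depth is positive.
* **Edge definition.** "Edge of the region" is read as the region's own
  boundary pixels (inner boundary); `delimit_hole(edge = "outer")`
  switches to the exterior ring for sensitivity analyses.
* **Auto-rejection.** Regions touching the image border, flat regions
  (depth ≤ 0), and holes with fewer than 3 pixels are rejected; at
  18.9 nm/px anything below 3 px is too small for a meaningful shape
  measurement. A manual rejection list is also honored, mirroring the
  semiautomated workflow.

# Hole morphometrics

For a hole of `n` pixels at pixel size `p`, the area is `A = n p^2` and
the **equivalent diameter** is the diameter of the circle of that area,
`d = 2 sqrt(A / pi)`. The **symmetry** builds the 2 × 2 covariance
matrix of the hole-pixel center coordinates; with eigenvalues
`lambda1 >= lambda2`, `s = sqrt(lambda2 / lambda1)` is the ratio of the
standard deviations along the minor and major principal axes
(rotation- and translation-invariant; 1 for anything with two equal
principal variances, e.g. 90°-rotation-symmetric shapes).

Two conventions are deliberate. The covariance uses the *population*
normalization (divide by `n`): a pixel set is a complete enumeration of
the hole, not a sample — for a solid `n`-pixel row this gives the exact
discrete-uniform variance `(n^2 - 1) / 12`. And the symmetry is the SD
ratio, not the variance ratio: the variance ratio
(`hole_symmetry(ratio = "variance")`) is provided for comparison, since
published descriptions of this statistic are ambiguous between the two.

`compare_groups()` performs a Kruskal–Wallis omnibus test
(`stats::kruskal.test`) and Dunn's pairwise z-tests on the joint ranks
with the standard tie correction, adjusted across all pairs (Bonferroni
by default; any `p.adjust` method can be selected). Medians and IQRs per
condition are reported alongside, which is how such hole statistics are
usually summarized.

# Tubule diameter fitting

A line profile drawn perpendicularly across a tubule (10 px wide, at
least 700 nm long by convention) is fitted with the projection of an
idealized labeling geometry convolved with a Lorentzian PSF — the
appropriate line shape for STED:

* **lumen labeling** (volume-filling marker, e.g. KDEL-targeted):
  chord projection of a filled disk, `P(x) = 2 sqrt(a^2 - x^2)`; the
  fitted diameter is the inner-leaflet distance;
* **surface labeling** (membrane marker, e.g. Sec61β-tagged): chord
  projection of an annulus of thickness 4.5 nm (direct protein tag) or
  17.5 nm (primary + secondary antibody); the fitted diameter is the
  outer-leaflet distance.

The fit is a nested grid search over diameter (default 20–200 nm, 1-nm
step) and PSF FWHM (default 20–100 nm, 0.5-nm step); the defaults
bracket all plausible live-cell values (tubules of ~48–144 nm, STED
FWHMs of ~45–55 nm). At each grid point the amplitude and background are
solved exactly by linear least squares — they are linear parameters, so
searching them would only add two axes of nuisance — and the profile
center is refined on a ±2-px sub-grid (0.5-px steps) around the
intensity-weighted centroid. Fitting operates on raw counts with
unweighted least squares. When the PSF is fixed instead of fitted,
`default_psf_fwhm()` supplies pooled per-labeling values
(50.9 nm membrane, 45.8 nm lumen).

The search is coarse-to-fine (a subsampled pass, then an exhaustive pass
at full grid resolution around the coarse optimum). The SSE surface is
smooth and single-welled over these ranges — verified by exhaustive maps
on noiseless profiles — so this reaches the full-grid optimum at a
fraction of the cost. `fit_ok` is withdrawn when the optimum sits on the
grid boundary or the amplitude fails to clear twice the residual SD, so
flat or pure-noise profiles are reported as failures rather than numbers.

The model kernel is the unit-area 1D Lorentzian truncated at 20 × FWHM
and renormalized; Lorentzian tails are heavy (about 1.6% of the mass
lies beyond 20 FWHM), and renormalization keeps the model's integral
exact so amplitude estimates are unbiased. The convolution is evaluated
as a discrete sum on a 1-nm grid.

# The nanohole simulator

`simulate_hole_field()` renders STED-like images of a labeled ER sheet
with torus-edged holes and full ground truth:

1. **Geometry.** A slab of thickness `t` (default 50 nm) whose holes are
   central cylinders of the requested inner diameter rimmed by the inner
   half of a torus with tube radius `t/2` — the only reading under which
   the rim is tangent to both slab faces. A column at distance `r` from
   a hole axis has luminal height 0 inside the inner radius,
   `2 sqrt((t/2)^2 - (R_h - r)^2)` across the rim (torus centerline
   `R_h = inner radius + t/2`), and `t` beyond.
2. **Voxelization.** Axial 1-nm voxels; lateral subpixels at 1/9 of the
   18.9-nm detector pixel (2.1-nm subpixels). Because the lumen is
   axially contiguous in every column, the 3D occupancy is stored as a
   per-column voxel count — exactly the 3D model summed along z without
   allocating ~10^9 voxels. Halving either resolution changes the
   expected image by well under 1% RMS; supersampling before
   downsampling suppresses aliasing of the sharp hole edges.
3. **Rendering.** Project (counts × `alpha`), area-average down to
   18.9-nm pixels, convolve with the PSF, add a constant background.
   Defaults `alpha = 10` per luminal voxel and background 1 give an
   interior sheet expectation of 501 counts.
4. **Noise.** The expected image is the per-pixel mean of independent
   Poisson draws; a single config seed deterministically governs both
   the sub-pixel center jitter (uniform ±0.5 px, which prevents
   every hole from sitting identically on the pixel grid) and the shot
   noise, so images are bit-reproducible.

The 2D PSF is the radially symmetric Lorentzian
`(b / 2 pi) (b^2 + rho^2)^(-3/2)` with `b = FWHM / 2`, truncated at
20 × FWHM and renormalized. This particular radial form is chosen
because its *line projection* is exactly the 1D Lorentzian of the same
FWHM — the quantity a profile-based PSF measurement reports — which
makes the simulator and the 1D tubule-fit model two independent
renderings of the same physics; on a noiseless simulated tubule they
agree to better than 1%. The superficially simpler radial extension
`1 / (b^2 + rho^2)` was rejected: its projection is √3 × wider than its
nominal FWHM and its 2D integral diverges.

The default field is 25 holes on a 5 × 5 grid spaced 105 px between
curved edges, with a batch mode (`simulate_hole_sweep()`) generating
four images each of 30-, 50-, 75-, 100-, 125-, 150-, and 200-nm inner
diameters. `sheet_intensity_ratio()` uses the same rendering chain to
relate sheet interior brightness to luminal thickness (the axial extent
of the ER lumen is far below the microscope's axial resolution, so
brightness is nearly proportional to thickness), and inverts the
monotone relation to estimate thickness from an observed ratio.

**What the simulator does and does not emulate.** It reproduces the
geometry, sampling, PSF shape, and shot-noise statistics of the
reference imaging conditions. It does not model detector read noise or
gain, depletion-beam artifacts, label stochasticity, sheet curvature or
thickness variation, or molecular motion during the dwell time. Passing
recovery tests on these images therefore validates the *algorithms*
(segmentation geometry, threshold rules, fit identifiability) — it does
not certify accuracy on real data, where labeling density and background
structure are less kind. One concrete instance: with the unit-area PSF
used here, even 30-nm holes retain a noise-free dip of ~100 counts
against ~6 counts of smoothed shot noise, so an algorithm given their
true centers keeps essentially all of them, whereas a human screening
noisy images misses many; small-hole attrition in manual workflows is a
perception effect that this pipeline does not (and does not try to)
model.

# Hole tracking

`track_hole()` operationalizes "manual tracking with local-minimum
center correction": frame by frame, the position snaps to the deepest
local minimum within a search radius (default 5 px ≈ 95 nm, under one
hole diameter) of the previous position. A hole is "present" when its
depth — ring-mean surround minus minimum — clears 20% of the
start-frame contrast; this threshold separates genuine disappearance
from shot-noise flicker and is exposed as a parameter. Single-frame
dropouts are bridged (gap tolerance 1 frame at ~70-ms framing, where
one-frame losses are shot-noise-plausible); longer absences end the
track. `classify_persistence()` then partitions a cohort into
persisted / appeared / disappeared / appeared-and-disappeared by
presence at the video bounds, and the summary fractions always sum to 1.

# The curvature budget

The analytic model represents an ER region as one disk-shaped sheet
(thickness `t`, rim modeled as the outer half-torus of tube radius
`r = t/2`), `n` nanoholes, and one cylindrical tubule of length `L`,
under a fixed total membrane area equal to that of the bare 5-µm
reference sheet — morphology changes must be paid for by resizing the
sheet disk, not by adding lipid. Closed forms:

* one hole adds inner-half-torus area `2 pi^2 R_h r - 4 pi r^2` of
  curved membrane and removes `2 pi R_h^2` of flat face area
  (both faces out to the torus centerline `R_h = inner radius + r`);
* the tubule adds lateral wall `pi d L` (no end cap) and its junction
  removes one cross-section `pi (d/2)^2` from the sheet rim — a
  second-order term retained for exact bookkeeping;
* the sheet radius solves the resulting quadratic in closed form, and
  the flat/curved split is reported; conservation holds to 1e-9
  relative by construction, and curved areas are reported without sign
  decomposition (hole rims are saddles; positive and negative principal
  curvature are not distinguished).

With `t = 50 nm` and 100-nm holes and tubule, the headline equivalence
is `equivalent_tubule_length(10) ≈ 928 nm`: ten nanoholes store the
curved membrane of about one micrometre of tubule, which is why
nanoholes are a plausible local reservoir for curvature-stabilizing
proteins. Isoclines of constant curved fraction in the `(n, L)` plane
are nearly linear (R² > 0.999 over the modeled range) with slope
`-equivalent_tubule_length(1)`, as the implicit-function view of the
affine budget predicts. The absolute curved *fraction* depends on the
rim and junction conventions above; the hole–tubule exchange rate does
not, which is why the equivalence is the quantity worth quoting.

# Problem sizes used in the tests

The test-suite simulations are sized to exercise every claim while
staying desk-scale: the full reference sweep (28 images of 25 holes) for
segmentation recovery, 200 seeded realizations of a 64 × 64 crop for the
Poisson consistency check, 50 noisy tubule profiles (on a 2-nm diameter
grid) for fit recovery, 1,000 random configurations for area
conservation, and 16 × 16 random fields for the watershed/brute-force
equivalence. The whole suite runs in about two minutes.

# Known limitations

* Hole selection is semiautomated by design: the package ranks and
  measures candidates but does not decide what is a hole; fully
  automatic classification is out of scope.
* The tubule model is 1D and assumes a straight, axially uniform tubule
  over the profile width; strongly curved or varicose tubules violate
  this.
* The curvature budget is purely geometric — no bending energies, no
  helicoidal connectors, no mechanics.
* Tracking uses a nearest-minimum motion model with no velocity prior;
  it is intended for the slow, dense hole motion regime, not for
  ballistic transport.
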
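# atriamesh

Multi-modal 3D geometry of the left atrium for atrial-fibrillation
substrate mapping. The package is aimed at cardiac electrophysiology and
image-analysis groups who need to combine an MRI-derived chamber geometry
with the ultrasound-derived reconstruction used by a non-contact
(charge-density) mapping system, and then compare conduction measurements
between the two.

It implements, in R with C++ kernels:

* **Contour-to-surface reconstruction** — a sparse stack of posed 2D
  endocardial contours (8 mm slice spacing) becomes a smooth closed
  triangular mesh: ruled-surface tubular initialisation, then iterative
  optimisation alternating attractor-based thin-plate-spline deformation
  with Laplacian smoothing, midpoint subdivision and quadric decimation.
  The deformation minimises `λ Σᵢ ‖F(Pᵢ) − Qᵢ′‖² + J(F)` with bounded
  attractor steps `Qᵢ′ = Pᵢ + β (Qᵢ − Pᵢ)/‖Qᵢ − Pᵢ‖`, where `J` is the 3-D
  second-order bending energy.
* **Point-cloud reconstruction** — an indicator-function Poisson solve
  (`∇²χ = ∇·V⃗` on a regular grid, marching-tetrahedra extraction) for
  intra-chamber-ultrasound style clouds, with 3-sd outlier trimming.
* **Registration** — generalized (plane-to-plane) ICP with per-point
  covariances, multi-start principal-axes initialisation and a
  non-increasing cost guarantee.
* **Comparison metrics** — directed/symmetric surface distance, enclosed
  volume (ml), surface area, sphere-based exclusion editing with hole
  capping, equivalent wall thickness `(V_outer − V_inner)/A_inner`.
* **Field analysis** — nearest-neighbour transfer of per-vertex conduction
  velocity (m/s) and pathological-conduction-pattern frequencies (1/s),
  area-weighted histograms with a 1.5 m/s CV threshold, Pearson/Spearman
  correlations, per-vertex distance to adjacent thoracic structures, the
  3 mm contact rule, and Mann–Whitney contact statistics.
* **Phantoms** — spheres, ellipsoids and a blended atrium (body + vein
  stubs + appendage pouch), sliced into contour stacks, sampled into
  dual-layer clouds, and decorated with conduction fields whose contact
  effect is known, so the whole pipeline is testable without patient data.

## Worked example

Reconstruct a noisy synthetic atrium from its contour stack, register it
onto an ultrasound-style reconstruction of the same chamber, and test
whether pathological-conduction frequencies are elevated at vertices in
contact with an adjacent structure:

```r
library(atriamesh)

spec  <- phantom_spec("blended_atrium", in_plane_noise_sd = 0.5, seed = 2)
truth <- make_phantom(spec)
cs    <- align_axial_stack(slice_to_contours(truth, spec))
fit   <- reconstruct(cs)
fit
#> Surface reconstruction from 7 contours
#>   mesh: 450 vertices, 896 faces, closed
#>   contour-to-mesh distance: 0.232 +/- 0.261 mm
#>   7 outer iterations, converged

icus <- decimate_mesh(truth, 1500L)          # stand-in for the catheter mesh
reg  <- generalized_icp(fit$mesh, icus)
reg
#> generalized ICP: RMS residual 2.279 mm after 6 iterations (converged)
#> rigid_transform: rotation angle 7.911 deg, translation  0.06574  0.67182 -0.04730 mm

cmp <- compare_reconstructions(apply_transform(fit$mesh, reg$transform), icus)
cmp$distance
#> surface distance (symmetric): 0.681 +/- 0.876 mm over 1202 points
c(cmp$volume_a_ml, cmp$volume_b_ml, cmp$relative_volume_pct)
#> 94.2 ml (contours) vs 100.6 ml (target); relative volume 93.6%

aorta <- make_tube(c(-36, -20, -20), c(-36, 20, 20), 6)   # adjacent structure
flds  <- make_fields(icus, aorta, effect = 3, duration_s = 60, seed = 3)
compare_by_contact(flds$lia, flds$proximity)
#> contact (n=30): 1.98 (IQR 1.82-2.08)
#> non-contact (n=722): 0.65 (IQR 0.567-0.717)
#> Mann-Whitney U = 21660, two-sided p = <2e-16
```

The contour fit sits well under the in-plane voxel size; the symmetric
surface distance between the two reconstructions is sub-millimetre after
registration; and the localized-irregular-activity frequency at contact
vertices is roughly three times the background, recovered highly
significantly — the effect size the field generator planted.

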
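---
title: "Left-atrial surface reconstruction, registration and conduction-field analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left-atrial surface reconstruction, registration and conduction-field analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriamesh)
```

## The problem

Charge-density mapping systems resolve whole-chamber conduction on a surface
mesh of the left atrium, but the chamber geometry they use is acquired with
an intra-chamber ultrasound catheter during the procedure. Cardiac MRI can
supply an independent, non-invasive geometry — as a sparse stack of 2D
endocardial contours (slices 8 mm apart, in-plane resolution a few mm) that
must be turned into a smooth closed surface, co-registered with the
catheter-derived reconstruction, and only then compared: geometrically
(surface distance, enclosed volume), and functionally (per-vertex conduction
velocity and the frequencies of pathological conduction patterns, including
their relation to adjacent thoracic structures such as the aorta and spine).

`atriamesh` implements that pipeline end to end, together with a phantom
module that generates synthetic contour stacks, ultrasound-style point
clouds and per-vertex fields with known ground truth, so every stage is
testable without patient data.

## Surface reconstruction from sparse contours

**Input.** An ordered stack of closed planar contours $\{C_j\}$, each with a
slice pose (origin plus two orthonormal in-plane axes, mm, global frame),
optionally one transverse contour, and two lid points closing the stack.

**Initial mesh.** Every contour is resampled to $K$ equally spaced vertices
(arc length, counter-clockwise winding, first vertex preserved). Consecutive
contours are joined as a ruled surface with triangle pairs
$(C_j^i, C_j^{i+1}, C_{j+1}^i)$, $(C_{j+1}^i, C_{j+1}^{i+1}, C_j^{i+1})$,
after rotating each ring's indexing to minimise total rung length (twist
minimisation); the extreme rings close onto the lid points with triangle
fans. The result is a closed, consistently oriented genus-0 mesh.

**Iterative deformation.** Attractor points $Q_i$ are drawn from the
contours by farthest-point sampling. Each outer cycle finds the closest
surface points $P_i$ (on triangles, not just vertices) and pulls with a
bounded step
$$Q_i' = P_i + \beta\,\frac{Q_i - P_i}{\lVert Q_i - P_i\rVert},$$
with the full-capture rule $Q_i' = Q_i$ whenever
$\lVert Q_i - P_i\rVert \le \beta$ (the unit direction is undefined at zero
distance). A volumetric thin-plate-spline deformation $F$ minimises
$$\lambda \sum_i \lVert F(P_i) - Q_i'\rVert^2 + J(F),$$
where $J$ is the 3-D second-order bending energy (kernel $\phi(r) = r$);
the regularised linear system carries $1/\lambda$ on the kernel diagonal, so
large $\lambda$ approaches interpolation and $\lambda \to 0$ the affine
least-squares fit. $F$ is applied to all mesh vertices under an orientation
guard: any step that would flip a face normal is halved (up to six times) —
a practical stand-in for a diffeomorphic application; a true velocity-field
integration is out of scope. Umbrella Laplacian smoothing
$p_i \leftarrow p_i + w\,\bigl(\tfrac{1}{|N_i|}\sum_{j\in N_i} p_j - p_i\bigr)$
follows each deformation, and every few cycles a midpoint subdivision plus
quadric-error decimation refreshes the mesh resolution. A cycle is accepted
only if the mean contour-to-mesh distance does not increase (worsening
cycles are rejected and the pull step halved), so the accepted distance
trace is non-increasing; iteration stops when the improvement falls below a
tolerance.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `K` | 64 | vertices/contour | resolves a 40–80 mm chamber cross-section to ~2–3 mm chords |
| `n_attractors` | 400 | points | dense, roughly uniform coverage of 6–10 contours |
| `beta` | 1.0 | mm | small relative to the 8 mm slice spacing, keeps deformations smooth |
| `lambda_` | 1e3 | – | strong data term while the kernel smooths between attractors |
| `smooth_weight`, `smooth_iters` | 0.3, 2 | – | gentle smoothing per cycle; heavier smoothing shrinks the chamber |
| `subdivision_interval` | 10 | cycles | refresh resolution once the shape has stabilised |
| `decimation_target_faces` | 6000 | faces | about 3000 vertices, the working resolution of clinical maps |
| `max_outer_iters`, `convergence_tol` | 50, 0.01 mm | – | distance improvements below 0.01 mm are far below voxel size |

### Numerical and geometric choices

* **Lid placement.** When lids are not supplied they sit at the extreme
  contour's centroid, offset outward along the stack axis by one full slice
  spacing. The chamber boundary lies somewhere in the one-spacing gap beyond
  the last slice with signal, and the cone fan closing the surface encloses
  less volume than the rounded cap it stands in for; a half-spacing apex
  provably underestimates chamber volume (for a 30 mm sphere sliced at 8 mm
  the ideal ruled solid is then 5.7% small), while the full-spacing apex
  brings the same solid within ~2–3%.
* **Slice alignment.** A transverse contour crossing the axial planes
  defines two crossing points per plane; each axial contour receives the
  in-plane rigid translation minimising the summed crossing-point-to-boundary
  distance (Nelder–Mead from a closest-point initial guess). Rotation is not
  adjusted — translation-only is the smallest correction consistent with the
  purpose, and the transverse slice constrains little else.
* **Farthest-point sampling** breaks ties towards the lowest candidate
  index, making attractor sets reproducible.
* **Degenerate inputs.** Contours need at least three distinct points;
  coplanar TPS control points raise a rank error; open meshes are rejected
  by volume computation with a pointer to hole capping.

## Point-cloud (Poisson) reconstruction

Ultrasound-style point clouds are fitted with an indicator-function Poisson
solver: per-point normals from k-NN PCA oriented away from the centroid,
trilinear splatting of the normal field $\vec V$ onto a regular grid
($2^{\text{depth}}$ cells per axis over a 1.5× padded bounding cube), a
spectral solve of $\nabla^2\chi = \nabla\cdot\vec V$ (FFT, with a 1.5-voxel
Gaussian prefilter), and marching-tetrahedra extraction at the mean
indicator value over the samples. Six tetrahedra per cube share the cube
diagonal, which makes the level set watertight; a breadth-first winding
repair restores global orientation consistency afterwards. Only the largest
component is kept and no smoothing is applied. Far outliers (mean-radius
deviation beyond 3 sd) are removed by `trim_cloud_outliers()` before
fitting, emulating the manual pre-cleaning of clinical clouds.

## Registration

`generalized_icp()` implements plane-to-plane ICP: per-point covariances
from 20-point neighbourhoods with the smallest eigenvalue replaced by
$\epsilon = 10^{-3}$, residuals weighted by
$(C^B_j + R\,C^A_i R^\top)^{-1}$, and a damped Gauss–Newton update on
$(\omega, t)$. The initial pose aligns centroids and principal axes; all
four proper axis-sign combinations are refined to convergence and the
lowest final cost wins, which resolves the sign ambiguity that a single
up-front choice gets wrong on near-symmetric chambers. The recorded cost is
the RMS nearest-neighbour residual after each full iteration; steps that
would increase it are halved, so the cost sequence is non-increasing by
construction even as correspondences change. The MRI-derived mesh is moved
onto the ultrasound-derived target (the mapping system's frame); the
inverse transform is stored alongside.

## Comparison metrics and field analysis

Surface distance is measured vertex-to-triangle in either direction; the
symmetric report averages the two directed means and pools the per-point
lists. Enclosed volume uses the divergence theorem on the outward-oriented
mesh (reported in ml); the equivalent wall thickness of two nested
reconstructions is $(V_\text{outer} - V_\text{inner})/A_\text{inner}$.
Note that for a genuinely curved shell this overestimates the geometric
thickness by roughly $t/r$, which matters when interpreting it on
chamber-scale shells.

Per-vertex fields (conduction velocity in m/s under three rhythm protocols;
pathological-conduction-pattern frequencies in 1/s) transfer between
co-registered meshes by nearest vertex (ties to the lowest index).
Area-weighted histograms give each vertex a barycentric third of its
incident triangle areas; conduction velocities above 1.5 m/s are excluded
(not winsorised) by default. Contact with an adjacent structure is
inclusive at the threshold (distance ≤ 3 mm) and a union over structures.
Group comparisons use the Mann–Whitney U test — exact for pooled n ≤ 20
without ties, normal approximation with continuity and tie corrections
otherwise (field sizes of ~3000 vertices make enumeration infeasible, and
Poisson-count fields are tie-heavy); correlations use Pearson (Fisher-z CI)
or Spearman computed as an average-rank transform followed by the Pearson
machinery; per-case volumes compare by paired t. Pooled-vertex analysis is
the default; per-case summaries can be built by applying the same functions
case-wise.

## The phantom module

`make_phantom()` builds a sphere, an ellipsoid (subdivided icosahedra, so
volumes are analytic to ~0.2%) or a blended atrium: an implicit smooth union
of an ellipsoid body, four short tapered ostial stubs standing in for
pulmonary veins and one lateral pouch for the appendage, meshed by marching
tetrahedra. The stubs are deliberately short: the slicing pipeline keeps
only the largest intersection loop per plane, so volume living in protruding
tubes is invisible to it by construction (the same is true of the clinical
pipeline, which excludes the veins before analysis).

`slice_to_contours()` emulates the axial acquisition: planes 8 mm apart
(matching a 2.8×2.8×8 mm³ voxel), the grid centred on the object — a
scanner grid positioned independently of the chamber does not place a
tangent plane exactly at its pole, and a tangent first slice is degenerate —
Gaussian in-plane jitter (default sd 0.5 mm, about a fifth of the in-plane
voxel), plus one mid-height transverse contour. `sample_cloud()` emulates
the ultrasound acquisition: area-weighted surface samples, Gaussian noise
along the normal (sd 0.5 mm), an optional epicardial reflection layer
displaced outward by 1.9 mm (the cohort-scale equivalent wall thickness),
and a configurable fraction of far outliers. `make_fields()` draws smooth
low-order angular conduction-velocity patterns in [0.2, 1.5] m/s and
Poisson event counts over a 60 s recording with base rates 0.05 (focal
firing), 0.15 (rotational), 0.65 (irregular) events/s, multiplied by an
`effect` (default 3) within 3 mm of a supplied structure. All generators
are deterministic under a fixed seed and leave the global RNG state
untouched.

**What the phantoms do not emulate:** real segmentation error is spatially
correlated, not i.i.d. Gaussian; ultrasound clouds have direction-dependent
density and dropout; conduction fields on real atria correlate with wall
structure rather than a known contact zone. Passing phantom tests therefore
demonstrates correctness of the geometry and statistics machinery under the
stated acquisition geometry, not clinical accuracy on patient data.

## Problem sizes used by the tests

The test-suite and the acceptance script run, by the package's own choice,
on: icosphere phantoms at subdivision 3–4 (642–2562 vertices), contour
stacks of 6–8 slices resampled at K = 64, registrations on ~1500–3000
vertex meshes, Poisson grids of 64³, 100 power-study and 200
null-calibration replicates on a 642-vertex chamber. These sizes keep every
stage at seconds while matching the ~3000-vertex working resolution of
clinical maps.

## Known limitations

* The diffeomorphic contract of the deformation is enforced only via the
  orientation guard; extreme steps are rejected rather than re-integrated.
* Poisson reconstruction uses a single-resolution spectral solve rather
  than an adaptive octree; memory grows as the cube of `depth` (default 64³).
* The equivalent-wall-thickness construction carries the $t/r$ curvature
  bias discussed above.
* Exclusion regions are spheres; clinically the regions are marked
  interactively, and a sphere is the simplest reproducible proxy.
* Decimation preserves manifoldness via link-condition and normal-flip
  checks but does not guarantee a global error bound on the simplified
  surface.
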
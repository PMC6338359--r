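---
title: "Sparse-contour surface reconstruction by bi-Laplacian fairing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-contour surface reconstruction by bi-Laplacian fairing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Manual slice-by-slice delineation of small anatomical structures — the
package is designed around the hippocampus on T1-weighted MRI — is accurate
but slow: a full hippocampus pair takes an expert one to two hours, spread
over roughly 20–40 slices depending on the outlining protocol. Because the
cross-section of a smooth structure changes little from slice to slice,
most of that effort is redundant. `fastsurf` reconstructs the full closed
surface from a *sparse* subset of delineated contours (as few as four, with
the two extreme slices always among them), by treating the missing rings of
vertices as unknowns of a discrete surface-fairing problem.

## The fairing model

The delineated contours are resampled to a common number of points `K` and
connected into a regular triangulated tube: between each pair of
consecutive known rings, `m` intermediate rings are inserted by linear
interpolation, and the band between adjacent rings is triangulated as quads
split along a fixed diagonal, giving every interior vertex exactly six
neighbours. Over this graph the uniform ("umbrella") Laplacian is

```
L[n, n] =  1
L[n, m] = -1 / N(n)    if m is a neighbour of vertex n
L[n, m] =  0           otherwise
```

where `N(n)` is the neighbour count, so every row sums to zero. Two
fairing orders are available:

* **Order 1 (membrane / spring network).** Requiring `L x = L y = L z = 0`
  at the unknown vertices is the force balance of a network of identical
  springs; the continuous analogue is a *minimal surface*. Minimal surfaces
  neck inward between fixed rings (soap-film behaviour) and put no penalty
  on the crease at the known contours.
* **Order 2 (thin plate, the default).** Requiring `L² x = L² y = L² z = 0`
  minimizes a discrete curvature energy instead; the continuous analogue is
  a *thin-plate surface*. The full `L` over all tube vertices — known rings
  included — is assembled before squaring, so bending across the known rings
  is penalized too; rows and columns are restricted to the unknowns only at
  solve time. This is what keeps the reconstruction flush with a cylinder
  where the membrane solution necks.

The three coordinate systems are solved independently. Known vertices are
never part of the unknown block, so delineated points are interpolated
*exactly* (bit-identical in the output).

### What the solver does

The restricted systems are sparse and non-symmetric; they are solved with
an unpreconditioned bi-conjugate gradient iteration started from the
linear-interpolation scaffold positions, to a relative residual of `1e-8`
with at most `10 N` iterations. On non-convergence the package falls back
to a direct sparse factorization (below 20 000 unknowns). Every solution is
verified against the residual before being accepted; failure raises a
classed error rather than returning a bad surface. On the default problem
size (7 contours × 100 points, 3 intermediate rings ≈ 1 800 unknowns) the
whole reconstruction takes well under a second on one core.

### Design choices where the formulation is open

Several details of the discrete setup are not forced by the model; the
package fixes them as follows.

* **Point correspondence across rings (twist).** Straight-line connection
  of consecutive rings presumes an index correspondence. Each ring starts
  at a canonical point (maximal first in-plane world coordinate, ties by
  the second), and the later ring of each gap is then cyclically re-indexed
  to minimize the total squared length of the connecting edges, searched
  exhaustively over all `K` offsets. This is deterministic and recovers,
  for example, an artificial 90° rotation of one ring exactly.
* **Quad split.** Always along the same diagonal `(i, j) → (i+1, j+1)`,
  giving the regular valence-6 interior.
* **End caps.** The surface is closed with triangle fans to the centroid of
  each extreme ring, displaced outward along the slicing axis by half a
  slice thickness: a delineation on the extreme slice asserts tissue on the
  whole slice, so a cap in the contour plane itself would systematically
  truncate the structure. Cap apices are fixed.
* **Fairing graph = tube only.** The cap fans close the output mesh but do
  not contribute to the energy graph. The apices are fixed and never
  adjacent to an unknown ring, so the membrane equations are unchanged;
  excluding the fans from `L` keeps the artificial rim between wall and cap
  out of the thin-plate energy, which would otherwise flare the tube
  outward near its ends.
* **Defaults.** 100 points per contour and 3 intermediate rings per gap.
  The package's own sweep (`run_sweep`) reproduces the rationale: overlap
  collapses below ~50 points per contour, plateaus above ~100, and depends
  only weakly (±0.02 Jaccard) on the intermediate-ring count between 1 and
  6.

## From label volumes to meshes

All geometry lives in world millimetres via the NIfTI voxel-to-world
affine (0-based voxel-centre indices), so metrics are independent of voxel
grids. Binary label volumes are converted to surfaces by isosurface
extraction at level 0.5 with marching tetrahedra on the Freudenthal
subdivision of the voxel grid: the subdivision is translation-invariant, so
the surface is watertight and consistently oriented by construction, with
no special-case tables. Edge crossings are located on the cell's
*trilinear* interpolant (bisection on the edge), so extracted vertices lie
on the same isosurface classic marching-cubes implementations approximate;
on rasterized analytic solids the enclosed volume agrees with a reference
marching-cubes implementation to a fraction of a percent. Labels are not
smoothed and meshes are not decimated.

Contours are extracted per slice at the 0.5 level of the binary slice
image (sub-voxel linear interpolation via `grDevices::contourLines`),
which is consistent with the 0.5-level surface extraction. Exactly one
closed contour per slice is allowed; slices with two foreground regions or
internal holes raise an error — irregular or cavitated shapes are outside
the model. Slicing is supported along the three voxel axes.

## Overlap and change metrics

Mesh agreement is measured by a grid-approximated Jaccard index: a regular
grid covers the joint bounding box padded by twice the spacing, and
`Jacc = N(A∩B) / N(A∪B)` over grid points inside each closed surface, with
`Dice = 2J/(1+J)`. Grid samples sit at *cell centres* so that samples do
not fall exactly on coincident axis-aligned faces, where any deterministic
boundary rule would bias the count; with cell-centred samples the analytic
half-overlap-cube case (`J = 1/3`) is resolved exactly at modest spacings.
The default spacing is 0.5 mm — half the smallest phantom voxel — and a
refinement test (halving the spacing changes the value by less than the
previous change) guards the approximation. Point containment uses vertical
ray parity with a rasterization-style half-open rule on shared projected
edges; points on the surface count as inside.

Volume differences are reported as cross-sectional percentage volume
difference `PVD = 2 (V_A − V_B)/(V_A + V_B) × 100` and longitudinal
percentage volume change `PVC = (V_bl − V_fu)/V_bl × 100` (positive =
shrinkage), with volumes from the divergence theorem over mesh faces.

## The synthetic phantoms

Because the reference datasets behind the method's published validation are
clinical and not redistributable, the package ships a phantom generator
that reproduces the *regime* of those data rather than any particular
subject: voxels of 1 × 1 × 1.2 mm, a hippocampus-like solid spanning ~20
slices along its long axis with a volume of 2–3.5 cm³, built as an
elliptical cross-section (default minor/major ratio 0.8) swept along a
C-shaped centerline (default total bend 60°) with a monotone head-to-tail
taper (8 → 5 mm). Analytic solids (sphere, ellipsoid, cylinder, box) carry
closed-form volumes for oracle tests. Rasterization happens at a fixed
generic sub-voxel grid offset: anatomy never aligns with the scanner
lattice, and an aligned lattice places whole rings of voxel centres exactly
on analytic boundaries, visibly biasing rasterized volumes.

Two perturbations emulate study designs:

* **Back-to-back pairs** (`make_btb_pair`): two rasterizations of the same
  shape with independent band-limited boundary jitter (low-order angular
  and axial modes only, so phantoms stay smooth; RMS amplitude `sigma` in
  mm). This emulates independent re-delineation of back-to-back scans and
  gives an unbiased "robustness" comparison: reconstruct from A's contours,
  compare against B's full surface, and vice versa. At `sigma = 0.5` mm the
  pairwise full-mesh Jaccard — the reproducibility ceiling no
  reconstruction can beat — lands around 0.8, comparable to intra-rater
  hippocampus re-delineation.
* **Longitudinal pairs** (`make_longitudinal_pair`): the follow-up scales
  every cross-section by `sqrt(1 − f)` before rasterization, so the
  continuous volume shrinks exactly by the atrophy fraction `f` and the
  pair is exactly co-registered.

What the phantoms deliberately do **not** emulate: image intensities and
their artefacts (the method never reads intensities), protocol-dependent
boundary definitions, inter-rater systematic offsets, and shapes with
multiple contours per slice or internal cavities. Passing phantom
experiments therefore demonstrates the geometric fidelity of the
reconstruction and metrics pipeline under the model's smoothness
assumptions — not performance on any particular clinical dataset.

## Experiment designs and problem sizes

`run_agreement` sweeps the number of input contours (minimum four) against
the full-label surface; `run_robustness` runs the unbiased back-to-back
design and reports the bias as agreement minus robustness; `run_atrophy`
and `run_atrophy_cohort` compare PVC from full meshes with PVC from
sparse reconstructions; `run_sweep` grids intermediate-ring count against
points per contour from 10 known contours. The shipped tests and the
acceptance script run these at desk scale — single phantoms, cohorts of
20, overlap grids at 0.5 mm — which keeps the full suite under a minute
while leaving the trends (monotone recovery in contour count, the
points-per-contour cliff and plateau, unit-slope atrophy recovery)
clearly resolved.

```{r example}
library(fastsurf)

vol <- make_phantom(phantom_spec("hippocampus", seed = 7))
full <- mesh_from_labels(vol)
stack <- select_sparse(resample_stack(extract_contours(vol)), 7)
mesh <- reconstruct(stack, order = 2)
compare_meshes(mesh, full, spacing = 0.5)
```

## Known limitations

* One closed contour per slice; no cavities. Severely atrophic or tumour-like
  shapes violate this.
* Blunt-ended structures lose part of the terminal half-slice to the domed
  cap: dense-contour self-reconstruction of a flat-ended tube converges to
  a Jaccard of ~0.91–0.93 against the label surface, versus ≳0.97 for
  smoothly closing shapes. This is a property of the contour representation
  (the surface beyond the extreme delineated plane is unobserved), not of
  the solver.
* Slicing along arbitrary oblique normals is not implemented; use the voxel
  axes.
* The graph Laplacian is combinatorial (uniform weights), as the fairing
  model prescribes — irregular point spacing is handled by resampling, not
  by cotangent weighting.
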
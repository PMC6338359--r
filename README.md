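# fastsurf

Reconstruction of closed anatomical surfaces from sparse planar contours by
discrete bi-Laplacian surface fairing, with mesh-based overlap and volumetry
metrics, synthetic phantoms, and simulation experiments.

## The problem

Slice-by-slice manual delineation of small structures — the package is
designed around the hippocampus on MRI — takes an expert one to two hours
per hippocampus pair, spread over ~20–40 slices. Since cross-sections change
slowly from slice to slice, a handful of delineated contours carries almost
all of the shape information. `fastsurf` completes the surface from as few
as four contours (the two extreme slices must be among them), in well under
a second, using only mesh processing: no intensities, atlases or shape
priors.

## The method

Delineated contours are resampled to `K` equally spaced points, connected
into a regular triangulated tube with interpolated intermediate rings, and
closed with end caps. Over the tube graph the uniform Laplacian is

    L[n,n] = 1,   L[n,m] = -1/N(n)  (m adjacent to n),   0 otherwise,

whose rows sum to zero. Unknown (intermediate) vertex positions solve the
sparse systems

    order 1:  L x = L y = L z = 0      (membrane / minimal surface)
    order 2:  L²x = L²y = L²z = 0      (thin plate — the default)

restricted to the unknowns, with the delineated points interpolated
exactly. Agreement between surfaces is measured with a grid-approximated
Jaccard index `J = N(A∩B)/N(A∪B)` (Dice `D = 2J/(1+J)`), and volumes with

    PVD = 2 (V_A - V_B) / (V_A + V_B) × 100        (cross-sectional, %)
    PVC = (V_bl - V_fu) / V_bl × 100               (longitudinal, %)

computed from closed meshes via the divergence theorem. Label volumes are
meshed by watertight marching tetrahedra at the 0.5 level with
trilinear-consistent edge crossings. See the methods vignette
(`vignettes/fastsurf-methods.Rmd`) for the full formulation and design
decisions.

## Worked example

```r
library(fastsurf)

# hippocampus-like phantom: 1 x 1 x 1.2 mm voxels, ~20 slices, ~2.6 cm^3
vol  <- make_phantom(phantom_spec("hippocampus", seed = 7))
full <- mesh_from_labels(vol)                 # reference surface from labels

# simulate sparse delineation: keep 7 of the ~20 slice contours
stack <- select_sparse(resample_stack(extract_contours(vol)), 7)

# thin-plate reconstruction from the 7 contours
mesh <- reconstruct(stack, order = 2)
compare_meshes(mesh, full, spacing = 0.5)
#> <metric_report> Jaccard 0.9285 (Dice 0.9629), PVD -2.59%, V_A 2501.1 mm^3, V_B 2566.7 mm^3
```

Reading the report: the 7-contour reconstruction overlaps the full-label
surface with a Jaccard index of 0.93 (Dice 0.96), and its volume is 2.6%
smaller (the terminal half-slices beyond the extreme contours are only
partially recovered by the end caps). With all ~20 contours the Jaccard
rises towards the grid/rasterization ceiling; with the minimum of 4 it
drops to ~0.91 on this phantom.

The same operations are scriptable from a shell via the thin CLI wrapper:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/fastsurf.R", package = "fastsurf"))')
Rscript $CLI simulate    --kind hippocampus --seed 7 --out phantom.nii.gz
Rscript $CLI reconstruct --contours stack.json --out mesh.ply
Rscript $CLI evaluate    --ref full.ply --test mesh.ply --out report.csv
Rscript $CLI experiment  agreement --config cfg.json --out results.csv
```

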
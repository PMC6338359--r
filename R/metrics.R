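# Mesh-based agreement and longitudinal change metrics: grid-approximated
# Jaccard, the Dice conversion, percentage volume difference (PVD) and
# percentage volume change (PVC).

#' Grid-approximated Jaccard overlap of two closed meshes
#'
#' The overlap of two surfaces is approximated on a fine regular grid
#' enclosing both: `Jacc = N_intersect / N_union`, the counts of grid points
#' inside both surfaces and inside their union. The grid covers the joint
#' bounding box padded by `2 * spacing`, with sample points placed at cell
#' centres so that samples do not sit exactly on coincident axis-aligned
#' boundaries. The same grid is used for both meshes, so the measure is
#' exactly symmetric.
#'
#' @param mesh_a,mesh_b closed [triangle_mesh] objects.
#' @param spacing grid spacing in mm (default 0.5).
#' @return An object of class `overlap_grid` with counts `n_a`, `n_b`,
#'   `n_intersection`, `n_union`, the `jaccard` value, and the grid
#'   parameters.
#' @export
jaccard_grid <- function(mesh_a, mesh_b, spacing = 0.5) {
  fs_stopifnot(spacing > 0, "spacing must be positive",
               "fastsurf_invalid_input")
  check_closed(mesh_a)
  check_closed(mesh_b)
  lo <- pmin(apply(mesh_a$vertices, 2, min), apply(mesh_b$vertices, 2, min))
  hi <- pmax(apply(mesh_a$vertices, 2, max), apply(mesh_b$vertices, 2, max))
  pad <- 2 * spacing
  origin <- lo - pad + spacing / 2
  dims <- pmax(1L, as.integer(floor((hi + pad - origin) / spacing)) + 1L)
  in_a <- cpp_grid_in_mesh(mesh_a$vertices, mesh_a$faces, origin, spacing,
                           dims)
  in_b <- cpp_grid_in_mesh(mesh_b$vertices, mesh_b$faces, origin, spacing,
                           dims)
  n_a <- sum(in_a)
  n_b <- sum(in_b)
  n_int <- sum(in_a & in_b)
  n_union <- n_a + n_b - n_int
  if (n_union == 0L)
    fs_abort("no grid point falls inside either mesh; grid too coarse or meshes degenerate",
             "fastsurf_grid_error")
  structure(list(spacing = spacing, origin = origin, dims = dims,
                 n_a = n_a, n_b = n_b, n_intersection = n_int,
                 n_union = n_union, jaccard = n_int / n_union),
            class = "overlap_grid")
}

#' @exportS3Method print overlap_grid
print.overlap_grid <- function(x, ...) {
  cat(sprintf("<overlap_grid> spacing %g mm, %s points, Jaccard %.4f\n",
              x$spacing, paste(x$dims, collapse = "x"), x$jaccard))
  invisible(x)
}

#' Dice overlap from a Jaccard index
#'
#' `D = 2 J / (J + 1)`; monotone on `[0, 1]` with fixed points 0 and 1.
#'
#' @param jaccard Jaccard index in `[0, 1]`.
#' @return The equivalent Dice index.
#' @export
dice_from_jaccard <- function(jaccard) {
  fs_stopifnot(all(jaccard >= 0 & jaccard <= 1),
               "jaccard must lie in [0, 1]", "fastsurf_domain_error")
  2 * jaccard / (1 + jaccard)
}

#' Jaccard index from a Dice overlap
#'
#' Inverse of [dice_from_jaccard]: `J = D / (2 - D)`.
#'
#' @param dice Dice index in `[0, 1]`.
#' @return The equivalent Jaccard index.
#' @export
jaccard_from_dice <- function(dice) {
  fs_stopifnot(all(dice >= 0 & dice <= 1), "dice must lie in [0, 1]",
               "fastsurf_domain_error")
  dice / (2 - dice)
}

#' Cross-sectional percentage volume difference
#'
#' `PVD(A, B) = 2 (V_A - V_B) / (V_A + V_B) * 100`; antisymmetric in its
#' arguments and bounded by +/- 200.
#'
#' @param v_a,v_b volumes in mm^3 with `v_a + v_b > 0`.
#' @return PVD in percent.
#' @export
pvd <- function(v_a, v_b) {
  fs_stopifnot(v_a + v_b > 0, "PVD requires v_a + v_b > 0",
               "fastsurf_domain_error")
  2 * (v_a - v_b) / (v_a + v_b) * 100
}

#' Longitudinal percentage volume change
#'
#' `PVC(A, B) = (V_A - V_B) / V_A * 100` from baseline A to follow-up B;
#' positive values mean shrinkage (atrophy).
#'
#' @param v_baseline baseline volume in mm^3 (> 0).
#' @param v_followup follow-up volume in mm^3.
#' @return PVC in percent.
#' @export
pvc <- function(v_baseline, v_followup) {
  fs_stopifnot(v_baseline > 0, "PVC requires a positive baseline volume",
               "fastsurf_domain_error")
  (v_baseline - v_followup) / v_baseline * 100
}

#' Full agreement report between two closed meshes
#'
#' Composes the grid Jaccard, the Dice conversion, mesh volumes and PVD into
#' one report. When a transform is supplied (e.g. a rigid registration
#' produced externally), it is applied to `mesh_a` before comparison.
#'
#' @param mesh_a,mesh_b closed [triangle_mesh] objects; `mesh_a` is listed
#'   first in the PVD sign convention.
#' @param spacing overlap-grid spacing in mm.
#' @param transform optional [affine_transform] applied to `mesh_a`.
#' @return An object of class `metric_report`: `jaccard`, `dice`, `pvd`,
#'   `volume_a`, `volume_b` (mm^3) and `spacing`.
#' @export
compare_meshes <- function(mesh_a, mesh_b, spacing = 0.5, transform = NULL) {
  if (!is.null(transform)) mesh_a <- apply_affine(mesh_a, transform)
  grid <- jaccard_grid(mesh_a, mesh_b, spacing)
  v_a <- mesh_volume(mesh_a)
  v_b <- mesh_volume(mesh_b)
  structure(list(jaccard = grid$jaccard,
                 dice = dice_from_jaccard(grid$jaccard),
                 pvd = pvd(v_a, v_b),
                 volume_a = v_a, volume_b = v_b,
                 spacing = spacing, grid = grid),
            class = "metric_report")
}

#' @exportS3Method print metric_report
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> Jaccard %.4f (Dice %.4f), PVD %+.2f%%, V_A %.1f mm^3, V_B %.1f mm^3\n",
              x$jaccard, x$dice, x$pvd, x$volume_a, x$volume_b))
  invisible(x)
}

#' @exportS3Method as.data.frame metric_report
as.data.frame.metric_report <- function(x, ...) {
  data.frame(jaccard = x$jaccard, dice = x$dice, pvd = x$pvd,
             volume_a = x$volume_a, volume_b = x$volume_b,
             spacing = x$spacing)
}
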
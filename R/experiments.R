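# Simulation experiments mirroring the validation designs: agreement versus
# number of input contours, back-to-back robustness, longitudinal atrophy
# recovery, and the intermediate-contour / points-per-contour parameter
# sweep. All outputs are plain data.frames; all runs are deterministic given
# the phantom spec and seeds.

#' Agreement between sparse reconstructions and the full segmentation
#'
#' For each contour count `k`, extracts all slice contours from the volume,
#' resamples them, keeps `k` at regular intervals, reconstructs the surface
#' by fairing, and compares it against the full-label surface mesh.
#'
#' @param vol a [label_volume].
#' @param n_contours integer vector of contour counts (each within
#'   `[4, slice count]`).
#' @param order fairing order (default 2, thin-plate).
#' @param spacing overlap-grid spacing in mm.
#' @param axis slicing axis.
#' @param points_per_contour,n_intermediate reconstruction parameters.
#' @return A data.frame with one row per `k`: `n_contours`, `jaccard`,
#'   `dice`, `pvd`, `volume_full`, `volume_fastsurf`, and an `error` column
#'   recording failures explicitly (NA on success).
#' @export
run_agreement <- function(vol, n_contours, order = 2, spacing = 0.5,
                          axis = 3, points_per_contour = 100L,
                          n_intermediate = 3L) {
  n_contours <- as.integer(n_contours)
  if (length(n_contours) == 0)
    return(data.frame(n_contours = integer(), jaccard = numeric(),
                      dice = numeric(), pvd = numeric(),
                      volume_full = numeric(), volume_fastsurf = numeric(),
                      error = character()))
  full_mesh <- mesh_from_labels(vol)
  stack <- resample_stack(
    extract_contours(vol, axis = axis,
                     points_per_contour = points_per_contour,
                     n_intermediate = n_intermediate))
  rows <- lapply(n_contours, function(k) {
    res <- tryCatch({
      sparse <- select_sparse(stack, k)
      mesh <- reconstruct(sparse, order = order)
      rep_ <- compare_meshes(mesh, full_mesh, spacing = spacing)
      data.frame(n_contours = k, jaccard = rep_$jaccard, dice = rep_$dice,
                 pvd = rep_$pvd, volume_full = rep_$volume_b,
                 volume_fastsurf = rep_$volume_a, error = NA_character_)
    }, fastsurf_error = function(e) {
      data.frame(n_contours = k, jaccard = NA_real_, dice = NA_real_,
                 pvd = NA_real_, volume_full = NA_real_,
                 volume_fastsurf = NA_real_, error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, rows)
}

#' Back-to-back robustness analysis
#'
#' Emulates the unbiased comparison available with back-to-back scans:
#' reconstructions from the contours of one member of a pair are compared
#' against the full mesh of the other member (and vice versa), which removes
#' the bias of comparing a reconstruction with the segmentation its own
#' contours came from. The full-mesh A-vs-B comparison (the re-delineation
#' reproducibility ceiling) and the biased agreement are reported alongside,
#' with `bias = agreement - robustness` on the Jaccard scale.
#'
#' @param vol_a,vol_b two [label_volume]s of the same underlying structure,
#'   pre-registered (e.g. from [make_btb_pair]).
#' @param k number of contours for the sparse reconstructions.
#' @param order fairing order.
#' @param spacing overlap-grid spacing in mm.
#' @param axis slicing axis.
#' @return A list with `robustness_ab`, `robustness_ba` (the two unbiased
#'   [compare_meshes] reports), `agreement_a`, `agreement_b` (biased),
#'   `ceiling` (full-mesh A vs B), and the scalar summaries
#'   `jaccard_robustness`, `jaccard_agreement`, `jaccard_ceiling`,
#'   `bias_jaccard`.
#' @export
run_robustness <- function(vol_a, vol_b, k = 7, order = 2, spacing = 0.5,
                           axis = 3) {
  mesh_a <- mesh_from_labels(vol_a)
  mesh_b <- mesh_from_labels(vol_b)
  rec_a <- reconstruct(select_sparse(resample_stack(
    extract_contours(vol_a, axis = axis)), k), order = order)
  rec_b <- reconstruct(select_sparse(resample_stack(
    extract_contours(vol_b, axis = axis)), k), order = order)

  rob_ab <- compare_meshes(rec_a, mesh_b, spacing = spacing)
  rob_ba <- compare_meshes(rec_b, mesh_a, spacing = spacing)
  agr_a <- compare_meshes(rec_a, mesh_a, spacing = spacing)
  agr_b <- compare_meshes(rec_b, mesh_b, spacing = spacing)
  ceiling_rep <- compare_meshes(mesh_a, mesh_b, spacing = spacing)

  jacc_rob <- mean(c(rob_ab$jaccard, rob_ba$jaccard))
  jacc_agr <- mean(c(agr_a$jaccard, agr_b$jaccard))
  list(robustness_ab = rob_ab, robustness_ba = rob_ba,
       agreement_a = agr_a, agreement_b = agr_b, ceiling = ceiling_rep,
       jaccard_robustness = jacc_rob, jaccard_agreement = jacc_agr,
       jaccard_ceiling = ceiling_rep$jaccard,
       bias_jaccard = jacc_agr - jacc_rob)
}

#' Atrophy-rate recovery from sparse reconstructions
#'
#' Computes the longitudinal percentage volume change ([pvc]) between a
#' baseline and a follow-up volume twice: from the full-label meshes and
#' from `k`-contour reconstructions of both time points.
#'
#' @param baseline,followup co-registered [label_volume]s (e.g. from
#'   [make_longitudinal_pair]).
#' @param k number of contours.
#' @param order fairing order.
#' @param axis slicing axis.
#' @return A one-row data.frame: `pvc_full`, `pvc_fastsurf`, and the four
#'   underlying volumes.
#' @export
run_atrophy <- function(baseline, followup, k = 7, order = 2, axis = 3) {
  rec_of <- function(vol) reconstruct(select_sparse(resample_stack(
    extract_contours(vol, axis = axis)), k), order = order)
  v_bl_full <- mesh_volume(mesh_from_labels(baseline))
  v_fu_full <- mesh_volume(mesh_from_labels(followup))
  v_bl_fs <- mesh_volume(rec_of(baseline))
  v_fu_fs <- mesh_volume(rec_of(followup))
  data.frame(pvc_full = pvc(v_bl_full, v_fu_full),
             pvc_fastsurf = pvc(v_bl_fs, v_fu_fs),
             volume_baseline_full = v_bl_full,
             volume_followup_full = v_fu_full,
             volume_baseline_fastsurf = v_bl_fs,
             volume_followup_fastsurf = v_fu_fs)
}

#' Atrophy recovery over a seeded phantom cohort
#'
#' Draws a cohort of hippocampus-like phantoms with atrophy fractions
#' spread over `atrophy_range`, measures PVC from full meshes and from
#' `k`-contour reconstructions, and reports the paired values.
#'
#' @param n_subjects cohort size (default 20).
#' @param atrophy_range range of true atrophy fractions (default
#'   `c(0, 0.1)`).
#' @param k number of contours.
#' @param order fairing order.
#' @param seed cohort seed.
#' @param base_spec template [phantom_spec] for the cohort.
#' @return A data.frame with one row per subject: `subject`,
#'   `atrophy_true_pct`, `pvc_full`, `pvc_fastsurf` and the volumes.
#' @export
run_atrophy_cohort <- function(n_subjects = 20, atrophy_range = c(0, 0.1),
                               k = 7, order = 2, seed = 1L,
                               base_spec = phantom_spec("hippocampus")) {
  fractions <- seq(atrophy_range[1], atrophy_range[2],
                   length.out = n_subjects)
  rows <- lapply(seq_len(n_subjects), function(i) {
    spec <- base_spec
    spec$seed <- as.integer(seed + i)
    spec$atrophy_fraction <- fractions[i]
    pair <- make_longitudinal_pair(spec)
    res <- run_atrophy(pair$baseline, pair$followup, k = k, order = order)
    cbind(data.frame(subject = i,
                     atrophy_true_pct = 100 * fractions[i]), res)
  })
  do.call(rbind, rows)
}

#' Parameter sweep: intermediate contours and points per contour
#'
#' From a fixed number of known contours (default 10, the tuning setup),
#' reconstructs the surface for every combination of intermediate-contour
#' count and points-per-contour and scores it against the full-label mesh.
#'
#' @param vol a [label_volume].
#' @param n_intermediate_range intermediate-contour counts (default 1:6).
#' @param points_range points-per-contour values (default
#'   `c(10, 50, 100, 200, 400)`).
#' @param n_known number of known contours (default 10).
#' @param order fairing order.
#' @param spacing overlap-grid spacing in mm.
#' @param axis slicing axis.
#' @return A data.frame with one row per grid cell: `n_intermediate`,
#'   `points_per_contour`, `jaccard`, `dice`, `pvd`.
#' @export
run_sweep <- function(vol, n_intermediate_range = 1:6,
                      points_range = c(10, 50, 100, 200, 400),
                      n_known = 10, order = 2, spacing = 0.5, axis = 3) {
  full_mesh <- mesh_from_labels(vol)
  raw <- extract_contours(vol, axis = axis)
  rows <- list()
  for (pts in points_range) {
    stack <- select_sparse(resample_stack(raw, pts), n_known)
    for (ni in n_intermediate_range) {
      mesh <- reconstruct(stack, order = order, n_intermediate = ni,
                          points_per_contour = pts)
      rep_ <- compare_meshes(mesh, full_mesh, spacing = spacing)
      rows[[length(rows) + 1L]] <-
        data.frame(n_intermediate = ni, points_per_contour = pts,
                   jaccard = rep_$jaccard, dice = rep_$dice, pvd = rep_$pvd)
    }
  }
  do.call(rbind, rows)
}
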
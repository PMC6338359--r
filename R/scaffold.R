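# Scaffold construction: known contour rings joined by straight-line bands
# through linearly interpolated intermediate rings, closed by centroid-apex
# end caps, triangulated as a regular band mesh.

# cyclic offset of ring Q (K x 3) minimizing total squared connecting-edge
# length to ring P; exhaustive over all K offsets
best_cyclic_offset <- function(p, q) {
  k <- nrow(p)
  # sum |P_i - Q_{i+o}|^2 = const - 2 * sum_i P_i . Q_{i+o}; maximize the dot
  best <- 0L
  best_dot <- -Inf
  for (o in 0:(k - 1)) {
    idx <- ((seq_len(k) - 1 + o) %% k) + 1
    d <- sum(p * q[idx, , drop = FALSE])
    if (d > best_dot) {
      best_dot <- d
      best <- o
    }
  }
  best
}

shift_ring <- function(q, o) {
  k <- nrow(q)
  q[((seq_len(k) - 1 + o) %% k) + 1, , drop = FALSE]
}

#' Build the triangulated scaffold connecting known contours
#'
#' Between each consecutive pair of known rings, `n_intermediate` rings are
#' inserted by linear interpolation of corresponding points at equal
#' fractions of the gap (the "parallel contours" initialization). Point
#' correspondence across each gap is fixed by the cyclic offset of the later
#' ring minimizing the total squared connecting-edge length (twist
#' minimization). Bands are triangulated as quads split along a fixed
#' diagonal, giving every interior vertex exactly 6 neighbours, and the
#' surface is closed by triangle fans to the two extreme-ring centroids.
#' Cap apices are marked known and stay fixed during fairing.
#'
#' @param stack a [contour_stack]; all contours must carry the same number
#'   of points (use [resample_stack] first).
#' @param n_intermediate intermediate rings per gap (>= 0); defaults to the
#'   stack's setting.
#' @return An object of class `scaffold_mesh`: a closed [triangle_mesh]
#'   plus `ring_index` (per-vertex ring id, 0 and `n_rings + 1` for the two
#'   apices), `known_mask`, `n_rings` and `n_points_per_ring`.
#' @export
build_scaffold <- function(stack, n_intermediate = stack$n_intermediate) {
  n_intermediate <- as.integer(n_intermediate)
  fs_stopifnot(n_intermediate >= 0, "n_intermediate must be >= 0",
               "fastsurf_scaffold_error")
  counts <- vapply(stack$contours, function(ct) nrow(ct$points), 0L)
  if (length(unique(counts)) != 1L)
    fs_abort("all contours must carry the same number of points",
             "fastsurf_scaffold_error")
  k <- counts[1]
  known_rings <- lapply(stack$contours, `[[`, "points")

  # twist-minimizing correspondence, applied cumulatively down the stack
  for (g in seq_len(length(known_rings) - 1)) {
    o <- best_cyclic_offset(known_rings[[g]], known_rings[[g + 1]])
    known_rings[[g + 1]] <- shift_ring(known_rings[[g + 1]], o)
  }

  rings <- list()
  ring_known <- logical(0)
  for (g in seq_len(length(known_rings) - 1)) {
    p <- known_rings[[g]]
    q <- known_rings[[g + 1]]
    rings[[length(rings) + 1L]] <- p
    ring_known <- c(ring_known, TRUE)
    if (n_intermediate > 0) {
      for (j in seq_len(n_intermediate)) {
        t <- j / (n_intermediate + 1)
        rings[[length(rings) + 1L]] <- (1 - t) * p + t * q
        ring_known <- c(ring_known, FALSE)
      }
    }
  }
  rings[[length(rings) + 1L]] <- known_rings[[length(known_rings)]]
  ring_known <- c(ring_known, TRUE)

  r <- length(rings)
  verts <- do.call(rbind, rings)
  # domed caps: the extreme delineated slice represents a full slice of
  # tissue, so each apex sits half a slice thickness beyond its ring plane
  # (slice thickness derived from the stack's plane coordinates)
  pc <- vapply(stack$contours, `[[`, 0, "plane_coord")
  si <- vapply(stack$contours, `[[`, 0L, "slice_index")
  dz <- (pc[length(pc)] - pc[1]) / max(si[length(si)] - si[1], 1L)
  e_axis <- c(0, 0, 0)
  e_axis[stack$axis] <- 1
  apex_lo <- colMeans(rings[[1]]) - dz / 2 * e_axis
  apex_hi <- colMeans(rings[[r]]) + dz / 2 * e_axis
  verts <- rbind(verts, apex_lo, apex_hi)
  rownames(verts) <- NULL
  n_ring_verts <- r * k
  i_apex_lo <- n_ring_verts + 1L
  i_apex_hi <- n_ring_verts + 2L

  vid <- function(ring, i) (ring - 1L) * k + ((i - 1L) %% k) + 1L
  faces <- matrix(0L, 2L * (r - 1L) * k + 2L * k, 3L)
  row <- 0L
  for (ring in seq_len(r - 1L)) {
    for (i in seq_len(k)) {
      # quad (ring,i)-(ring,i+1)-(ring+1,i+1)-(ring+1,i), fixed diagonal
      faces[row + 1L, ] <- c(vid(ring, i), vid(ring, i + 1L),
                             vid(ring + 1L, i + 1L))
      faces[row + 2L, ] <- c(vid(ring, i), vid(ring + 1L, i + 1L),
                             vid(ring + 1L, i))
      row <- row + 2L
    }
  }
  for (i in seq_len(k)) {
    faces[row + 1L, ] <- c(i_apex_lo, vid(1L, i + 1L), vid(1L, i))
    faces[row + 2L, ] <- c(i_apex_hi, vid(r, i), vid(r, i + 1L))
    row <- row + 2L
  }

  mesh <- triangle_mesh(verts, faces, check = FALSE)
  if (mesh_volume_unchecked(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]

  ring_index <- c(rep(seq_len(r), each = k), 0L, r + 1L)
  known_mask <- c(rep(ring_known, each = k), TRUE, TRUE)
  structure(list(mesh = mesh, ring_index = ring_index,
                 known_mask = known_mask, n_rings = r,
                 n_points_per_ring = k, axis = stack$axis),
            class = "scaffold_mesh")
}

# signed volume without the watertightness check (used during construction)
mesh_volume_unchecked <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' @exportS3Method print scaffold_mesh
print.scaffold_mesh <- function(x, ...) {
  cat(sprintf("<scaffold_mesh> %d rings x %d points (+2 apices), %d known vertices\n",
              x$n_rings, x$n_points_per_ring, sum(x$known_mask)))
  invisible(x)
}
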
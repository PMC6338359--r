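# Planar contour stacks: extraction from label volumes, equal arc-length
# resampling, and sparse selection emulating partial manual outlining.

axis_index <- function(axis) {
  if (is.character(axis)) {
    axis <- match.arg(tolower(axis),
                      c("sagittal", "coronal", "axial", "x", "y", "z"))
    axis <- switch(axis, sagittal = 1L, coronal = 2L, axial = 3L,
                   x = 1L, y = 2L, z = 3L)
  }
  axis <- as.integer(axis)
  fs_stopifnot(axis %in% 1:3, "axis must name one of the three voxel axes",
               "fastsurf_invalid_input")
  axis
}

# right-handed in-plane axis pair (u, v) with u x v = +axis
inplane_axes <- function(a) switch(a, c(2L, 3L), c(3L, 1L), c(1L, 2L))
# canonical-start axis pair: first/second remaining axis in (x, y, z) order
canon_axes <- function(a) switch(a, c(2L, 3L), c(1L, 3L), c(1L, 2L))

polygon_signed_area <- function(u, v) {
  u2 <- c(u[-1], u[1])
  v2 <- c(v[-1], v[1])
  sum(u * v2 - u2 * v) / 2
}

#' Planar closed contour
#'
#' A closed polyline tracing a structure's perimeter on one slice. Points
#' are stored open (the closing segment from last back to first is implicit)
#' and the winding is canonicalized counter-clockwise when viewed down the
#' positive slicing axis.
#'
#' @param points K x 3 matrix of world-mm coordinates, K >= 3.
#' @param slice_index integer slice position along the slicing axis.
#' @param plane_coord world-mm coordinate of the slice plane along the axis.
#' @param role `"known"` (delineated) or `"intermediate"` (to be faired).
#' @param axis slicing axis: 1/2/3 or `"sagittal"`/`"coronal"`/`"axial"`.
#' @return An object of class `planar_contour`.
#' @export
planar_contour <- function(points, slice_index, plane_coord,
                           role = c("known", "intermediate"), axis = 3) {
  role <- match.arg(role)
  axis <- axis_index(axis)
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) >= 2 &&
      max(abs(points[1, ] - points[nrow(points), ])) == 0)
    points <- points[-nrow(points), , drop = FALSE]
  fs_stopifnot(nrow(points) >= 3, "a contour needs at least 3 points",
               "fastsurf_degenerate_contour")
  steps <- rbind(diff(points), points[1, ] - points[nrow(points), ])
  fs_stopifnot(all(rowSums(steps^2) > 0),
               "consecutive contour points must be distinct",
               "fastsurf_degenerate_contour")
  uv <- inplane_axes(axis)
  if (polygon_signed_area(points[, uv[1]], points[, uv[2]]) < 0)
    points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  structure(list(points = points, slice_index = as.integer(slice_index),
                 plane_coord = as.numeric(plane_coord), role = role,
                 axis = axis),
            class = "planar_contour")
}

contour_perimeter <- function(contour) {
  p <- contour$points
  closed <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(closed)^2)))
}

contour_area <- function(contour) {
  uv <- inplane_axes(contour$axis)
  abs(polygon_signed_area(contour$points[, uv[1]], contour$points[, uv[2]]))
}

#' Ordered stack of planar contours along a slicing axis
#'
#' @param contours list of [planar_contour] objects, ordered by
#'   `plane_coord` (strictly increasing, one contour per slice).
#' @param axis the common slicing axis.
#' @param points_per_contour target number of points per contour used by the
#'   reconstruction (default 100).
#' @param n_intermediate number of intermediate contours inserted per gap
#'   between consecutive known contours during scaffolding (default 3).
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(contours, axis = 3, points_per_contour = 100L,
                          n_intermediate = 3L) {
  axis <- axis_index(axis)
  fs_stopifnot(length(contours) >= 2, "a stack needs at least 2 contours",
               "fastsurf_invalid_input")
  fs_stopifnot(all(vapply(contours, inherits, TRUE, "planar_contour")),
               "contours must be planar_contour objects",
               "fastsurf_invalid_input")
  pc <- vapply(contours, `[[`, 0, "plane_coord")
  fs_stopifnot(all(diff(pc) > 0),
               "plane_coords must be strictly increasing (one contour per slice)",
               "fastsurf_invalid_input")
  si <- vapply(contours, `[[`, 0L, "slice_index")
  fs_stopifnot(all(diff(si) > 0), "slice indices must be strictly increasing",
               "fastsurf_invalid_input")
  roles <- vapply(contours, `[[`, "", "role")
  fs_stopifnot(roles[1] == "known" && roles[length(roles)] == "known",
               "the extreme slices must carry known contours",
               "fastsurf_invalid_input")
  structure(list(contours = contours, axis = axis,
                 points_per_contour = as.integer(points_per_contour),
                 n_intermediate = as.integer(n_intermediate)),
            class = "contour_stack")
}

#' @exportS3Method print contour_stack
print.contour_stack <- function(x, ...) {
  roles <- vapply(x$contours, `[[`, "", "role")
  cat(sprintf("<contour_stack> %d contours along axis %d (%d known), %d pts/contour, %d intermediate/gap\n",
              length(x$contours), x$axis, sum(roles == "known"),
              x$points_per_contour, x$n_intermediate))
  invisible(x)
}

#' Extract per-slice contours from a label volume
#'
#' Traces the 0.5-level iso-contour of each occupied binary slice along the
#' slicing axis (sub-voxel, linear interpolation, consistent with the 0.5
#' iso-level of the surface extraction) and maps it to world mm. Every
#' extracted contour has role `"known"`; sparsification is a separate step
#' ([select_sparse]).
#'
#' @param vol a [label_volume] whose foreground is a single 26-connected
#'   component.
#' @param axis slicing axis (voxel axis 1/2/3 or
#'   `"sagittal"`/`"coronal"`/`"axial"`); default the third voxel axis.
#' @param points_per_contour,n_intermediate stored on the returned stack as
#'   reconstruction defaults.
#' @return A [contour_stack]. Slices whose foreground cross-section is not a
#'   single simply-connected region raise an error: the delineation model
#'   allows exactly one closed contour per slice.
#' @export
extract_contours <- function(vol, axis = 3, points_per_contour = 100L,
                             n_intermediate = 3L) {
  axis <- axis_index(axis)
  validate_label_volume(vol)
  uv <- inplane_axes(axis)
  d <- dim(vol$data)
  occupied <- which(apply(vol$data > 0, axis, any))
  contours <- vector("list", length(occupied))
  for (ci in seq_along(occupied)) {
    s <- occupied[ci]
    sl <- switch(axis,
                 vol$data[s, , ], vol$data[, s, ], vol$data[, , s])
    # orient the slice as (u, v) of the right-handed in-plane pair
    if (axis == 2L) sl <- t(sl)
    nu <- dim(sl)[1]; nv <- dim(sl)[2]
    padded <- matrix(0, nu + 2, nv + 2)
    padded[2:(nu + 1), 2:(nv + 1)] <- sl
    cl <- grDevices::contourLines(x = seq(-1, nu), y = seq(-1, nv),
                                  z = padded, levels = 0.5)
    if (length(cl) != 1L)
      fs_abort(sprintf(
        "slice %d has %d iso-contours; exactly one closed contour per slice is supported",
        s, length(cl)), "fastsurf_multi_contour_slice")
    u <- cl[[1]]$x
    v <- cl[[1]]$y
    if (u[1] == u[length(u)] && v[1] == v[length(v)]) {
      u <- u[-length(u)]
      v <- v[-length(v)]
    }
    idx <- matrix(0, length(u), 3)
    idx[, uv[1]] <- u
    idx[, uv[2]] <- v
    idx[, axis] <- s - 1  # 0-based
    world <- voxel_to_world(vol, idx)
    plane_coord <- mean(world[, axis])
    world[, axis] <- plane_coord
    contours[[ci]] <- planar_contour(world, slice_index = s - 1L,
                                     plane_coord = plane_coord,
                                     role = "known", axis = axis)
  }
  ord <- order(vapply(contours, `[[`, 0, "plane_coord"))
  contour_stack(contours[ord], axis = axis,
                points_per_contour = points_per_contour,
                n_intermediate = n_intermediate)
}

#' Resample a contour to equally spaced points
#'
#' Linearly interpolates `n_points` points at equal arc-length spacing along
#' the closed polyline, starting from the input point nearest the canonical
#' start (the input point with maximal coordinate along the first axis
#' orthogonal to the slicing axis, ties broken by the second). The canonical
#' start makes point indices comparable across contours of a stack.
#'
#' @param contour a [planar_contour].
#' @param n_points number of output points (>= 3).
#' @return A resampled [planar_contour].
#' @export
resample_contour <- function(contour, n_points) {
  n_points <- as.integer(n_points)
  fs_stopifnot(n_points >= 3, "n_points must be >= 3",
               "fastsurf_invalid_input")
  p <- contour$points
  ca <- canon_axes(contour$axis)
  start <- order(-p[, ca[1]], -p[, ca[2]])[1]
  if (start > 1) p <- p[c(start:nrow(p), 1:(start - 1)), , drop = FALSE]
  closed <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  total <- sum(seg)
  if (total <= 0)
    fs_abort("contour has zero perimeter", "fastsurf_degenerate_contour")
  s <- c(0, cumsum(seg))
  target <- total * (seq_len(n_points) - 1) / n_points
  out <- matrix(0, n_points, 3)
  for (d in 1:3)
    out[, d] <- stats::approx(s, closed[, d], xout = target,
                              method = "linear", ties = "ordered")$y
  out[, contour$axis] <- contour$plane_coord
  planar_contour(out, contour$slice_index, contour$plane_coord,
                 role = contour$role, axis = contour$axis)
}

#' Resample every contour of a stack
#'
#' @param stack a [contour_stack].
#' @param n_points points per contour; defaults to the stack's
#'   `points_per_contour`.
#' @return The resampled [contour_stack].
#' @export
resample_stack <- function(stack, n_points = stack$points_per_contour) {
  contours <- lapply(stack$contours, resample_contour, n_points = n_points)
  contour_stack(contours, axis = stack$axis,
                points_per_contour = n_points,
                n_intermediate = stack$n_intermediate)
}

#' Select a sparse subset of contours at regular intervals
#'
#' Keeps the two extreme slices (the reconstruction requires them) plus
#' `n_known - 2` further slices as evenly spaced as possible: kept positions
#' are `round(i * (S - 1) / (k - 1))` for `i = 0 .. k-1` over the `S`
#' occupied slices, with halves rounded up. Dropped slices are not retained;
#' intermediate rings are regenerated by the fairing step.
#'
#' @param stack a [contour_stack] (all roles known).
#' @param n_known number of contours to keep, between 4 and the number of
#'   slices.
#' @return A sparse [contour_stack] with `n_known` known contours.
#' @export
select_sparse <- function(stack, n_known) {
  n_known <- as.integer(n_known)
  s <- length(stack$contours)
  if (n_known < 4L)
    fs_abort("at least four contours are required",
             "fastsurf_too_few_contours")
  if (n_known > s)
    fs_abort(sprintf("n_known = %d exceeds the %d available slices",
                     n_known, s), "fastsurf_too_many_contours")
  i <- seq_len(n_known) - 1
  keep <- unique(floor(i * (s - 1) / (n_known - 1) + 0.5)) + 1
  if (length(keep) < 4L)
    fs_abort("even-interval selection collapsed below four contours",
             "fastsurf_too_few_contours")
  contours <- stack$contours[keep]
  contours <- lapply(contours, function(ct) { ct$role <- "known"; ct })
  contour_stack(contours, axis = stack$axis,
                points_per_contour = stack$points_per_contour,
                n_intermediate = stack$n_intermediate)
}

#' Write a contour stack to JSON
#'
#' Schema: `{axis: [ux,uy,uz], points_per_contour, n_intermediate,
#' contours: [{slice_index, plane_coord, role, points: [[x,y,z], ...]}]}`.
#'
#' @param stack a [contour_stack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contour_stack <- function(stack, path) {
  axis_vec <- c(0, 0, 0)
  axis_vec[stack$axis] <- 1
  obj <- list(
    axis = axis_vec,
    points_per_contour = stack$points_per_contour,
    n_intermediate = stack$n_intermediate,
    contours = lapply(stack$contours, function(ct)
      list(slice_index = ct$slice_index, plane_coord = ct$plane_coord,
           role = ct$role, points = ct$points)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour stack from JSON
#'
#' @param path path to a JSON file in the [write_contour_stack] schema. All
#'   stack invariants are re-validated on read.
#' @return A [contour_stack].
#' @export
read_contour_stack <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  axis_vec <- as.numeric(obj$axis)
  axis <- which(abs(axis_vec) > 0.5)
  fs_stopifnot(length(axis) == 1 && axis_vec[axis] > 0,
               "axis must be a positive unit vector along a principal axis",
               "fastsurf_invalid_input")
  contours <- lapply(obj$contours, function(ct) {
    pts <- ct$points
    if (!is.matrix(pts)) pts <- do.call(rbind, lapply(pts, as.numeric))
    planar_contour(pts, slice_index = ct$slice_index,
                   plane_coord = ct$plane_coord,
                   role = ct$role, axis = axis)
  })
  contour_stack(contours, axis = axis,
                points_per_contour = obj$points_per_contour,
                n_intermediate = obj$n_intermediate)
}

#' Per-contour perimeter and area summary
#'
#' @param stack a [contour_stack].
#' @return A data.frame with one row per contour: `slice_index`,
#'   `plane_coord`, `role`, `n_points`, `perimeter_mm`, `area_mm2`.
#' @export
contour_summary <- function(stack) {
  data.frame(
    slice_index = vapply(stack$contours, `[[`, 0L, "slice_index"),
    plane_coord = vapply(stack$contours, `[[`, 0, "plane_coord"),
    role = vapply(stack$contours, `[[`, "", "role"),
    n_points = vapply(stack$contours, function(ct) nrow(ct$points), 0L),
    perimeter_mm = vapply(stack$contours, contour_perimeter, 0),
    area_mm2 = vapply(stack$contours, contour_area, 0))
}
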
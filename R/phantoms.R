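# Synthetic phantoms: analytic solids and a hippocampus-like curved, tapered
# tube, rasterized to binary label volumes, with optional band-limited
# boundary jitter (emulating independent re-delineation of back-to-back
# scans) and exact pre-rasterization atrophy scaling.

#' Specification of a synthetic phantom
#'
#' All phantoms are represented as a planar cross-section profile swept
#' along the third (slicing) axis, which makes every occupied slice a single
#' simply-connected region -- the geometry the one-contour-per-slice
#' delineation model assumes. Sizes are in mm.
#'
#' @param kind `"sphere"`, `"ellipsoid"`, `"cylinder"`, `"box"` or
#'   `"hippocampus"`.
#' @param radius sphere/cylinder radius.
#' @param radii ellipsoid semi-axes (3).
#' @param sides box side lengths (3).
#' @param height cylinder height.
#' @param length hippocampus extent along the slicing axis (default 24 mm,
#'   about 20 slices at 1.2 mm thickness).
#' @param head_radius,tail_radius hippocampus cross-section major semi-axis
#'   at the two ends (monotone taper between them; defaults 8 and 5 mm).
#' @param ellipticity ratio of minor to major cross-section semi-axis
#'   (default 0.8).
#' @param bend_angle total turn angle of the C-shaped centerline in degrees
#'   (default 60); the in-plane sagitta follows the circular-arc relation.
#' @param spacing voxel size in mm (default `c(1, 1, 1.2)`: 1 mm^2 in-plane
#'   pixels with 1.2 mm slice thickness).
#' @param sigma boundary jitter amplitude in mm (RMS radial displacement,
#'   default 0; band-limited low-order angular/axial modes, so jittered
#'   phantoms stay smooth).
#' @param atrophy_fraction relative volume loss in `[0, 0.5]` applied to the
#'   continuous shape before rasterization (cross-sections scaled by
#'   `sqrt(1 - f)`, so the volume scales exactly by `1 - f`).
#' @param seed integer seed controlling the jitter field; identical spec and
#'   seed give bit-identical volumes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("hippocampus", "sphere", "ellipsoid",
                                  "cylinder", "box"),
                         radius = 8, radii = c(12, 9, 12.6),
                         sides = c(10, 10, 12), height = 16,
                         length = 24, head_radius = 8, tail_radius = 5,
                         ellipticity = 0.8, bend_angle = 60,
                         spacing = c(1, 1, 1.2), sigma = 0,
                         atrophy_fraction = 0, seed = 1L) {
  kind <- match.arg(kind)
  fs_stopifnot(all(c(radius, radii, sides, height, length, head_radius,
                     tail_radius, ellipticity, spacing) > 0),
               "all phantom sizes must be positive", "fastsurf_spec_error")
  fs_stopifnot(sigma >= 0, "sigma must be >= 0", "fastsurf_spec_error")
  fs_stopifnot(atrophy_fraction >= 0 && atrophy_fraction <= 0.5,
               "atrophy_fraction must lie in [0, 0.5]",
               "fastsurf_spec_error")
  structure(list(kind = kind, radius = radius, radii = radii, sides = sides,
                 height = height, length = length,
                 head_radius = head_radius, tail_radius = tail_radius,
                 ellipticity = ellipticity, bend_angle = bend_angle,
                 spacing = spacing, sigma = sigma,
                 atrophy_fraction = atrophy_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run expr with a local RNG state seeded from `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# swept-profile description: z extent, per-z cross-section parameters
profile_of <- function(spec) {
  switch(spec$kind,
    sphere = list(
      zlen = 2 * spec$radius,
      cross = function(t) {
        h <- pmax(1 - (2 * t - 1)^2, 0)
        r <- spec$radius * sqrt(h)
        list(cx = 0, cy = 0, a = r, b = r, shape = "ellipse")
      },
      volume = 4 / 3 * pi * spec$radius^3),
    ellipsoid = list(
      zlen = 2 * spec$radii[3],
      cross = function(t) {
        h <- pmax(1 - (2 * t - 1)^2, 0)
        list(cx = 0, cy = 0, a = spec$radii[1] * sqrt(h),
             b = spec$radii[2] * sqrt(h), shape = "ellipse")
      },
      volume = 4 / 3 * pi * prod(spec$radii)),
    cylinder = list(
      zlen = spec$height,
      cross = function(t)
        list(cx = 0, cy = 0, a = spec$radius, b = spec$radius,
             shape = "ellipse"),
      volume = pi * spec$radius^2 * spec$height),
    box = list(
      zlen = spec$sides[3],
      cross = function(t)
        list(cx = 0, cy = 0, a = spec$sides[1] / 2, b = spec$sides[2] / 2,
             shape = "rect"),
      volume = prod(spec$sides)),
    hippocampus = {
      sagitta <- spec$length / 2 * tan(spec$bend_angle * pi / 180 / 4)
      h <- spec$head_radius
      tl <- spec$tail_radius
      list(
        zlen = spec$length,
        cross = function(t) {
          a <- h + (tl - h) * t
          list(cx = sagitta * sin(pi * t), cy = 0,
               a = a, b = spec$ellipticity * a, shape = "ellipse")
        },
        # V = integral of pi * a(t) * b(t) over the length; a linear in t
        volume = pi * spec$ellipticity * spec$length *
          (h^2 + h * tl + tl^2) / 3)
    })
}

# band-limited radial jitter field in mm as a function of (theta, t);
# amplitude calibrated so the RMS displacement over the boundary equals sigma
make_jitter_field <- function(sigma, seed) {
  if (sigma == 0)
    return(function(theta, t) rep(0, length(theta)))
  with_local_seed(seed, {
    modes_m <- 1:3
    modes_n <- 0:2
    coef <- array(stats::rnorm(2 * length(modes_m) * length(modes_n)),
                  c(2, length(modes_m), length(modes_n)))
    field <- function(theta, t) {
      out <- numeric(length(theta))
      for (mi in seq_along(modes_m)) for (ni in seq_along(modes_n)) {
        axial <- cos(modes_n[ni] * pi * t)
        out <- out + axial * (coef[1, mi, ni] * cos(modes_m[mi] * theta) +
                              coef[2, mi, ni] * sin(modes_m[mi] * theta))
      }
      out
    }
    tg <- as.matrix(expand.grid(theta = seq(0, 2 * pi, length.out = 64),
                                t = seq(0, 1, length.out = 33)))
    rms <- sqrt(mean(field(tg[, 1], tg[, 2])^2))
    scale <- sigma / rms
    function(theta, t) scale * field(theta, t)
  })
}

#' Rasterize a phantom specification to a label volume
#'
#' The continuous shape (including jitter and atrophy scaling) is evaluated
#' at voxel centres. Analytic solids carry their closed-form volume as the
#' `analytic_volume` attribute; for jittered phantoms this is the volume of
#' the unjittered shape (the jitter is mean-zero).
#'
#' @param spec a [phantom_spec].
#' @param jitter_seed override for the jitter RNG seed (defaults to
#'   `spec$seed`); used to draw independent re-delineations of the same
#'   underlying shape.
#' @return A [label_volume] with attributes `analytic_volume` (mm^3) and
#'   `spec`.
#' @export
make_phantom <- function(spec, jitter_seed = spec$seed) {
  fs_stopifnot(inherits(spec, "phantom_spec"), "not a phantom_spec",
               "fastsurf_spec_error")
  prof <- profile_of(spec)
  jit <- make_jitter_field(spec$sigma, jitter_seed)
  shrink <- sqrt(1 - spec$atrophy_fraction)

  # world bounds from the swept profile
  ts <- seq(0, 1, length.out = 65)
  cs <- lapply(ts, prof$cross)
  amax <- max(vapply(cs, function(c_) c_$a, 0))
  xr <- range(vapply(cs, function(c_) c_$cx, 0)) + c(-1, 1) * (amax + 4 * spec$sigma + 2)
  bmax <- max(vapply(cs, function(c_) c_$b, 0))
  yr <- c(-1, 1) * (bmax + 4 * spec$sigma + 2)
  zr <- c(-2 * spec$spacing[3], prof$zlen + 2 * spec$spacing[3])
  if (prof$zlen / spec$spacing[3] > 400 || diff(xr) / spec$spacing[1] > 400)
    fs_abort("phantom exceeds supported volume bounds",
             "fastsurf_spec_error")

  # generic in-plane grid alignment: real structures never align with the
  # voxel lattice, and an aligned lattice places whole rings of voxel
  # centres exactly on analytic boundaries, biasing rasterized volumes
  xr[1] <- xr[1] - 0.37 * spec$spacing[1]
  yr[1] <- yr[1] - 0.29 * spec$spacing[2]
  zr[1] <- zr[1] - 0.43 * spec$spacing[3]
  nx <- ceiling(diff(xr) / spec$spacing[1]) + 2
  ny <- ceiling(diff(yr) / spec$spacing[2]) + 2
  nz <- ceiling(diff(zr) / spec$spacing[3]) + 2
  affine <- diag(c(spec$spacing, 1))
  affine[1:3, 4] <- c(xr[1], yr[1], zr[1])

  xs <- xr[1] + (seq_len(nx) - 1) * spec$spacing[1]
  ys <- yr[1] + (seq_len(ny) - 1) * spec$spacing[2]
  zs <- zr[1] + (seq_len(nz) - 1) * spec$spacing[3]

  data <- array(0L, c(nx, ny, nz))
  xy <- as.matrix(expand.grid(x = xs, y = ys))
  for (k in seq_len(nz)) {
    t <- zs[k] / prof$zlen
    if (t < 0 || t > 1) next
    c_ <- prof$cross(t)
    if (c_$a <= 0 || c_$b <= 0) next
    dx <- xy[, 1] - c_$cx
    dy <- xy[, 2] - c_$cy
    rn <- if (identical(c_$shape, "rect")) {
      pmax(abs(dx) / c_$a, abs(dy) / c_$b)
    } else {
      sqrt((dx / c_$a)^2 + (dy / c_$b)^2)
    }
    bound <- shrink
    if (spec$sigma > 0) {
      theta <- atan2(dy / c_$b, dx / c_$a)
      rbar <- sqrt(c_$a * c_$b)
      bound <- shrink * (1 + jit(theta, rep(t, length(theta))) / rbar)
    }
    data[, , k] <- as.integer(rn < bound)
  }

  vol <- label_volume(data, affine = affine)
  attr(vol, "analytic_volume") <- prof$volume * (1 - spec$atrophy_fraction)
  attr(vol, "spec") <- spec
  vol
}

#' Generate a back-to-back phantom pair
#'
#' Two rasterizations of the same underlying shape with independent
#' band-limited boundary jitter of amplitude `sigma`, emulating the
#' independent processing of back-to-back scans (intra-rater
#' re-delineation). The pairwise overlap decreases as `sigma` grows.
#'
#' @param spec a [phantom_spec] with `sigma > 0` (with `sigma = 0` the two
#'   volumes are identical).
#' @return A list of two [label_volume]s, `a` and `b`.
#' @export
make_btb_pair <- function(spec) {
  fs_stopifnot(inherits(spec, "phantom_spec"), "not a phantom_spec",
               "fastsurf_spec_error")
  list(a = make_phantom(spec, jitter_seed = spec$seed * 2L + 1L),
       b = make_phantom(spec, jitter_seed = spec$seed * 2L + 2L))
}

#' Generate a co-registered baseline / follow-up phantom pair
#'
#' The baseline is the spec with no atrophy; the follow-up applies the
#' spec's `atrophy_fraction` to the same underlying shape (same jitter
#' field), so the pair is exactly co-registered and the true volume change
#' is `atrophy_fraction * 100` percent.
#'
#' @param spec a [phantom_spec].
#' @return A list of two [label_volume]s, `baseline` and `followup`.
#' @export
make_longitudinal_pair <- function(spec) {
  base_spec <- spec
  base_spec$atrophy_fraction <- 0
  list(baseline = make_phantom(base_spec), followup = make_phantom(spec))
}

#' Serialize a phantom spec to JSON
#' @param spec a [phantom_spec].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom spec from JSON
#' @param path JSON path written by [write_phantom_spec] (or hand-written;
#'   missing fields fall back to the defaults).
#' @return A [phantom_spec].
#' @export
read_phantom_spec <- function(path) {
  obj <- jsonlite::fromJSON(path)
  args <- obj[names(obj) %in% names(formals(phantom_spec))]
  do.call(phantom_spec, args)
}
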
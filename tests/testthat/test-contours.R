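test_that("cylinder slices give one near-circular contour per slice", {
  vol <- make_phantom(phantom_spec("cylinder", radius = 6, height = 14.4))
  stack <- extract_contours(vol)
  expect_length(stack$contours, 12)
  for (ct in stack$contours) {
    ctr <- colMeans(ct$points)
    radii <- sqrt(rowSums(sweep(ct$points[, 1:2], 2, ctr[1:2])^2))
    expect_lt(abs(mean(radii) - 6) / 6, 0.06)
    expect_lt(abs(fastsurf:::contour_area(ct) - pi * 36) / (pi * 36), 0.05)
  }
})

test_that("sphere contour size peaks at the equatorial slice", {
  vol <- make_phantom(phantom_spec("sphere", radius = 8, spacing = c(1, 1, 1)))
  stack <- extract_contours(vol)
  areas <- vapply(stack$contours, fastsurf:::contour_area, 0)
  n <- length(areas)
  expect_lte(abs(which.max(areas) - (n + 1) / 2), 1)
})

test_that("a slice with a hole or two regions violates the one-contour rule", {
  annulus <- array(0L, c(17, 17, 4))
  xy <- sqrt(outer((0:16 - 8)^2, (0:16 - 8)^2, "+"))
  ring <- xy >= 2.5 & xy <= 7
  for (k in 1:4) annulus[, , k][ring] <- 1L
  expect_error(extract_contours(label_volume(annulus)),
               class = "fastsurf_multi_contour_slice")

  twoblob <- array(0L, c(13, 7, 6))
  twoblob[2:4, 2:5, 2:5] <- 1L
  twoblob[9:11, 2:5, 2:5] <- 1L
  # two in-plane blobs connected through a bridge on other slices
  twoblob[2:11, 2:5, 2] <- 1L
  expect_error(extract_contours(label_volume(twoblob)),
               class = "fastsurf_multi_contour_slice")
})

test_that("resampling a square places points at corners and midpoints", {
  sq <- planar_contour(cbind(c(2, -2, -2, 2), c(2, 2, -2, -2), 0),
                       0, 0, "known", axis = 3)
  rs <- resample_contour(sq, 8)
  expect_equal(nrow(rs$points), 8)
  # canonical start: maximal +x, ties broken by maximal +y
  expect_equal(rs$points[1, 1:2], c(2, 2))
  seg <- sqrt(rowSums(diff(rbind(rs$points, rs$points[1, ]))^2))
  expect_equal(seg, rep(2, 8))
  expect_true(all(abs(rs$points[, 1:2]) %in% c(0, 2)))
})

test_that("resampling an already-uniform contour is idempotent", {
  ct <- circle_contour(r = 3, z = 1, n = 48)
  rs <- resample_contour(ct, 48)
  expect_lt(max(abs(rs$points - resample_contour(rs, 48)$points)), 1e-9)
})

test_that("resampled circle points stay within the chord error bound", {
  ct <- circle_contour(r = 1, z = 0, n = 100)
  rs <- resample_contour(ct, 100)
  radii <- sqrt(rowSums(rs$points[, 1:2]^2))
  expect_true(all(abs(radii - 1) <= (1 - cos(pi / 100)) + 1e-12))
})

test_that("resampling preserves perimeter on smooth contours", {
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  smooth <- list(
    planar_contour(cbind(7 * cos(th), 4 * sin(th), 0), 0, 0, "known", 3),
    planar_contour(cbind((5 + cos(3 * th)) * cos(th),
                         (5 + cos(3 * th)) * sin(th), 2), 2, 2, "known", 3))
  for (ct in smooth) {
    for (n in c(32, 100)) {
      rs <- resample_contour(ct, n)
      expect_lt(abs(fastsurf:::contour_perimeter(rs) -
                    fastsurf:::contour_perimeter(ct)) /
                fastsurf:::contour_perimeter(ct), 0.01)
    }
  }
})

test_that("degenerate resampling inputs are rejected", {
  ct <- circle_contour(r = 1, z = 0, n = 12)
  expect_error(resample_contour(ct, 2), class = "fastsurf_invalid_input")
  expect_error(planar_contour(matrix(1, 3, 3), 0, 0, "known", 3),
               class = "fastsurf_degenerate_contour")
})

test_that("sparse selection keeps extremes at regular intervals", {
  mkstack <- function(s)
    ring_stack(rep(1, s), seq_len(s) - 1, n = 12)
  idx <- function(st) vapply(st$contours, `[[`, 0L, "slice_index")

  expect_equal(idx(select_sparse(mkstack(21), 5)), c(0L, 5L, 10L, 15L, 20L))
  expect_equal(idx(select_sparse(mkstack(20), 4)), c(0L, 6L, 13L, 19L))
  # identity when all slices are kept
  expect_equal(idx(select_sparse(mkstack(9), 9)), 0:8)
  expect_error(select_sparse(mkstack(10), 3),
               class = "fastsurf_too_few_contours")
  expect_error(select_sparse(mkstack(10), 11),
               class = "fastsurf_too_many_contours")
})

test_that("sparse selection is invariant under plane-coordinate shifts", {
  st <- ring_stack(rep(1, 15), seq_len(15) - 1, n = 12)
  shifted <- st
  shifted$contours <- lapply(st$contours, function(ct) {
    ct$plane_coord <- ct$plane_coord + 132.5
    ct$points[, 3] <- ct$points[, 3] + 132.5
    ct
  })
  shifted <- contour_stack(shifted$contours, axis = 3,
                           points_per_contour = st$points_per_contour,
                           n_intermediate = st$n_intermediate)
  i1 <- vapply(select_sparse(st, 6)$contours, `[[`, 0L, "slice_index")
  i2 <- vapply(select_sparse(shifted, 6)$contours, `[[`, 0L, "slice_index")
  expect_equal(i1, i2)
})

test_that("contour stacks survive a JSON round-trip with invariants intact", {
  vol <- make_phantom(phantom_spec("hippocampus"))
  stack <- resample_stack(extract_contours(vol), 40)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_contour_stack(stack, path)
  back <- read_contour_stack(path)
  expect_equal(length(back$contours), length(stack$contours))
  expect_equal(back$points_per_contour, stack$points_per_contour)
  for (i in seq_along(stack$contours))
    expect_lt(max(abs(back$contours[[i]]$points - stack$contours[[i]]$points)),
              1e-9)
})

test_that("contour summary reports perimeter and area per slice", {
  vol <- make_phantom(phantom_spec("cylinder", radius = 6, height = 14.4))
  s <- contour_summary(extract_contours(vol))
  expect_equal(nrow(s), 12)
  expect_true(all(s$perimeter_mm > 0 & s$area_mm2 > 0))
  expect_true(all(diff(s$plane_coord) > 0))
})
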
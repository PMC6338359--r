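test_that("the scaffold of two 100-point rings has the regular structure", {
  stack <- ring_stack(c(1, 1), c(0, 4), n = 100, n_intermediate = 3)
  sc <- build_scaffold(stack)
  expect_equal(sc$n_rings, 5)
  expect_equal(nrow(sc$mesh$vertices), 502)   # 5 rings x 100 + 2 apices
  v <- nrow(sc$mesh$vertices)
  f <- nrow(sc$mesh$faces)
  e <- 3 * f / 2                              # closed triangle mesh
  expect_equal(v - e + f, 2)                  # Euler characteristic
  expect_true(is_watertight(sc$mesh))
  expect_gt(mesh_volume(sc$mesh), 0)

  # valence: interior ring vertices 6, apices n_points_per_ring
  from <- c(sc$mesh$faces[, 1], sc$mesh$faces[, 2], sc$mesh$faces[, 3])
  to <- c(sc$mesh$faces[, 2], sc$mesh$faces[, 3], sc$mesh$faces[, 1])
  deg <- table(c(from, to)) / 2
  interior <- which(sc$ring_index %in% 2:4)
  expect_true(all(deg[as.character(interior)] == 6))
  apices <- which(sc$ring_index %in% c(0L, sc$n_rings + 1L))
  expect_true(all(deg[as.character(apices)] == 100))
  expect_true(all(sc$known_mask[apices]))
})

test_that("identical coaxial rings interpolate linearly before fairing", {
  stack <- ring_stack(c(2, 2), c(0, 4), n = 36, n_intermediate = 3)
  sc <- build_scaffold(stack)
  for (r in 2:4) {
    ring <- sc$mesh$vertices[sc$ring_index == r, ]
    expect_equal(unique(round(ring[, 3], 9)), r - 1)
    expect_equal(sqrt(rowSums(ring[, 1:2]^2)), rep(2, 36))
  }
})

test_that("twist minimization recovers an index-space rotation", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  p <- cbind(cos(th), sin(th), 0)
  q <- cbind(cos(th), sin(th), 2)[((0:99 + 25) %% 100) + 1, ]  # 90 degrees
  o <- fastsurf:::best_cyclic_offset(p, q)
  expect_equal(fastsurf:::shift_ring(q, o)[, 1:2], p[, 1:2])
  # connecting edges of the scaffold are near-vertical
  c1 <- planar_contour(p, 0, 0, "known", 3)
  c2 <- planar_contour(q, 2, 2, "known", 3)
  sc <- build_scaffold(contour_stack(list(c1, c2), 3, 100L, 0L))
  band <- sc$mesh$vertices[sc$ring_index == 2, ] -
    sc$mesh$vertices[sc$ring_index == 1, ]
  expect_lt(max(sqrt(rowSums(band[, 1:2]^2))), 0.1)
})

test_that("mismatched ring point counts are a scaffold error", {
  c1 <- circle_contour(1, 0, 24)
  c2 <- circle_contour(1, 2, 36)
  st <- contour_stack(list(c1, c2), 3, 24L, 3L)
  expect_error(build_scaffold(st), class = "fastsurf_scaffold_error")
})

test_that("the assembled Laplacian has the umbrella-operator structure", {
  stack <- ring_stack(c(1.5, 1.2, 1.8), c(0, 3, 6), n = 20,
                      n_intermediate = 2)
  sc <- build_scaffold(stack)
  for (order in 1:2) {
    sys <- build_laplacian(sc, order)
    L <- sys$L
    expect_equal(unname(Matrix::diag(L)), rep(1, nrow(L)))
    expect_lt(max(abs(Matrix::rowSums(L))), 1e-12)
    # off-diagonals: -1/N_neighbours at adjacency
    Ld <- as.matrix(L)
    diag(Ld) <- 0
    deg <- rowSums(Ld != 0)
    for (i in which(deg > 0))
      expect_true(all(Ld[i, Ld[i, ] != 0] == -1 / deg[i]))
  }
})

test_that("the sparse bi-Laplacian matches a dense matrix-product oracle", {
  stack <- ring_stack(c(1, 1.4), c(0, 2), n = 10, n_intermediate = 1)
  sc <- build_scaffold(stack)   # 30 ring vertices + 2 apices
  sys2 <- build_laplacian(sc, 2)
  L_dense <- dense_laplacian_oracle(sc)
  expect_lt(max(abs(as.matrix(sys2$L) - L_dense)), 1e-12)
  expect_lt(max(abs(as.matrix(sys2$S) - L_dense %*% L_dense)), 1e-12)
})

test_that("harmonic fairing respects the discrete maximum principle", {
  set.seed(7)
  radii <- runif(4, 0.8, 2.2)
  stack <- ring_stack(radii, c(0, 2, 5, 7), n = 40, n_intermediate = 3)
  sc <- build_scaffold(stack)
  faired <- solve_fairing(build_laplacian(sc, 1), sc)
  known <- sc$mesh$vertices[sc$known_mask, ]
  for (d in 1:3) {
    expect_gte(min(faired$vertices[, d]), min(known[, d]) - 1e-9)
    expect_lte(max(faired$vertices[, d]), max(known[, d]) + 1e-9)
  }
})

test_that("order 1 necks inward and order 2 follows the cylinder", {
  stack <- ring_stack(c(1, 1), c(0, 4), n = 100, n_intermediate = 3)
  sc <- build_scaffold(stack)
  f1 <- solve_fairing(build_laplacian(sc, 1), sc)
  f2 <- solve_fairing(build_laplacian(sc, 2), sc)
  mid <- sc$ring_index %in% 2:4
  r1 <- mean(sqrt(rowSums(f1$vertices[mid, 1:2]^2)))
  r2 <- mean(sqrt(rowSums(f2$vertices[mid, 1:2]^2)))
  expect_lt(r1, 1)                 # minimal surface necks inward
  expect_lt(r1, r2)                # thin plate stays closer to the ends
  expect_lte(r2, 1 + 1e-6)
  # agreement with the independent dense solves
  expect_lt(max(abs(f1$vertices - dense_fair_oracle(sc, 1))), 1e-6)
  expect_lt(max(abs(f2$vertices - dense_fair_oracle(sc, 2))), 1e-6)
})

test_that("the iterative solve matches the dense direct oracle", {
  set.seed(3)
  stack <- ring_stack(runif(5, 1, 2.5), c(0, 2, 4, 7, 9), n = 30,
                      n_intermediate = 3)
  sc <- build_scaffold(stack)   # 510 ring vertices + 2 apices < 1k
  for (order in 1:2) {
    sys <- build_laplacian(sc, order)
    got <- solve_fairing(sys, sc, method = "bicg")
    oracle <- dense_fair_oracle(sc, order)
    expect_lt(max(abs(got$vertices - oracle)), 1e-6)
  }
})

test_that("known vertices are interpolated exactly", {
  stack <- ring_stack(c(1.2, 0.9, 1.6), c(0, 3, 6), n = 50,
                      n_intermediate = 3)
  sc <- build_scaffold(stack)
  for (order in 1:2) {
    faired <- solve_fairing(build_laplacian(sc, order), sc)
    expect_identical(faired$vertices[sc$known_mask, ],
                     sc$mesh$vertices[sc$known_mask, ])
  }
})

test_that("rotationally symmetric input yields a symmetric solution", {
  stack <- ring_stack(c(1, 2, 1), c(0, 3, 6), n = 60, n_intermediate = 3)
  sc <- build_scaffold(stack)
  faired <- solve_fairing(build_laplacian(sc, 2), sc)
  for (r in seq_len(sc$n_rings)) {
    ring <- faired$vertices[sc$ring_index == r, ]
    radii <- sqrt(rowSums(ring[, 1:2]^2))
    expect_lt(diff(range(radii)), 1e-6)
    expect_lt(diff(range(ring[, 3])), 1e-6)
  }
})

test_that("reconstruction from dense contours reproduces the label surface", {
  vol <- make_phantom(phantom_spec("ellipsoid"))
  full <- mesh_from_labels(vol)
  stack <- resample_stack(extract_contours(vol))
  dense <- reconstruct(stack, n_intermediate = 0)
  expect_true(is_watertight(dense))
  expect_gte(jaccard_grid(dense, full, 0.5)$jaccard, 0.95)
})

test_that("reconstruction stays valid at the four-contour minimum", {
  vol <- make_phantom(phantom_spec("hippocampus"))
  stack <- select_sparse(resample_stack(extract_contours(vol)), 4)
  mesh <- reconstruct(stack)
  expect_true(is_watertight(mesh))
  expect_gt(mesh_volume(mesh), 0)
})
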
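test_that("mesh_volume is exact on cubes and invariant under translation", {
  m <- unit_cube_mesh()
  expect_equal(mesh_volume(m), 1.0)
  shifted <- apply_affine(m, {
    a <- diag(4); a[1:3, 4] <- c(100, -50, 7); a
  })
  expect_equal(mesh_volume(shifted), 1.0)
})

test_that("mesh_volume approaches the analytic sphere volume on an icosphere", {
  m <- icosphere(r = 1, subdivisions = 4)
  expect_lt(abs(mesh_volume(m) - 4 * pi / 3) / (4 * pi / 3), 0.005)
})

test_that("mesh_volume refuses open surfaces", {
  m <- unit_cube_mesh()
  open_mesh <- triangle_mesh(m$vertices, m$faces[-1, ], check = FALSE)
  expect_error(mesh_volume(open_mesh), class = "fastsurf_open_surface")
  expect_false(is_watertight(open_mesh))
  expect_true(is_watertight(m))
})

test_that("isosurface extraction recovers analytic volumes from labels", {
  # 20^3 voxels of 0.5 mm: a 10 mm cube
  vol <- label_volume(array(1L, c(20, 20, 20)), spacing = c(0.5, 0.5, 0.5))
  m <- mesh_from_labels(vol)
  expect_true(is_watertight(m))
  expect_lt(abs(mesh_volume(m) - 1000) / 1000, 0.05)

  sph <- make_phantom(phantom_spec("sphere", radius = 8, spacing = c(1, 1, 1)))
  ms <- mesh_from_labels(sph)
  expect_true(is_watertight(ms))
  expect_lt(abs(mesh_volume(ms) - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3),
            0.02)
})

test_that("isosurface extraction rejects empty and multi-component input", {
  empty <- label_volume(array(0L, c(5, 5, 5)))
  expect_error(mesh_from_labels(empty), class = "fastsurf_empty_segmentation")
  two <- array(0L, c(9, 5, 5))
  two[1:2, 2:3, 2:3] <- 1L
  two[7:8, 2:3, 2:3] <- 1L
  expect_error(mesh_from_labels(label_volume(two)),
               class = "fastsurf_multi_component")
})

test_that("labelled volume errors on invalid construction", {
  expect_error(label_volume(matrix(0, 2, 2)), class = "fastsurf_error")
  expect_error(label_volume(array(0, c(2, 2, 2)), affine = diag(3)),
               class = "fastsurf_error")
})

test_that("extraction error decreases monotonically with voxel size", {
  errs <- vapply(c(2, 1, 0.5), function(h) {
    vol <- make_phantom(phantom_spec("sphere", radius = 8,
                                     spacing = rep(h, 3)))
    abs(mesh_volume(mesh_from_labels(vol)) / (4 / 3 * pi * 512) - 1)
  }, 0)
  expect_true(all(diff(errs) <= 0))
  errs_box <- vapply(c(2, 1, 0.5), function(h) {
    vol <- make_phantom(phantom_spec("box", sides = c(10, 10, 12),
                                     spacing = rep(h, 3)))
    abs(mesh_volume(mesh_from_labels(vol)) / 1200 - 1)
  }, 0)
  expect_true(all(diff(errs_box) <= 0))
})

test_that("point containment matches the analytic sphere membership test", {
  m <- icosphere(r = 8, subdivisions = 3)
  set.seed(42)
  pts <- matrix(runif(3000, -10, 10), ncol = 3)
  inside <- contains_points(m, pts)
  analytic <- sqrt(rowSums(pts^2)) < 8
  expect_gte(mean(inside == analytic), 0.995)
})

test_that("point containment handles boundary points deterministically", {
  m <- unit_cube_mesh()
  expect_true(contains_points(m, matrix(c(0.5, 0.5, 0.5), 1)))
  expect_false(contains_points(m, matrix(c(10, 10, 10), 1)))
  # the mesh's own vertices lie on the surface: inside, by convention
  expect_true(all(contains_points(m, m$vertices)))
  expect_true(all(contains_points(m, matrix(c(0.5, 0.5, 0, 0, 0.5, 0.5),
                                            2, byrow = TRUE))))
  expect_error(contains_points(triangle_mesh(m$vertices, m$faces[-1, ],
                                             check = FALSE),
                               matrix(0, 1, 3)),
               class = "fastsurf_open_surface")
})

test_that("point containment agrees with the voxel-membership oracle", {
  vol <- make_phantom(phantom_spec("sphere", radius = 8, spacing = c(1, 1, 1)))
  m <- mesh_from_labels(vol)
  d <- dim(vol$data)
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  world <- voxel_to_world(vol, idx)
  inside <- contains_points(m, world)
  lab <- as.logical(vol$data)
  expect_gte(mean(inside == lab), 0.995)
  # disagreements only within one voxel of the surface: a disagreeing voxel
  # must have a neighbour with the opposite label
  dis <- which(inside != lab)
  if (length(dis) > 0) {
    for (i in dis) {
      nb_idx <- sweep(as.matrix(expand.grid(-1:1, -1:1, -1:1)), 2,
                      as.numeric(idx[i, ]), "+")
      ok <- nb_idx[, 1] >= 0 & nb_idx[, 1] < d[1] &
        nb_idx[, 2] >= 0 & nb_idx[, 2] < d[2] &
        nb_idx[, 3] >= 0 & nb_idx[, 3] < d[3]
      nb <- nb_idx[ok, , drop = FALSE] + 1
      vals <- vol$data[cbind(nb[, 1], nb[, 2], nb[, 3])]
      expect_true(any(vals != vol$data[idx[i, 1] + 1, idx[i, 2] + 1,
                                       idx[i, 3] + 1]))
    }
  }
})

test_that("affine application transforms volume as expected", {
  m <- unit_cube_mesh()
  expect_equal(apply_affine(m, diag(4))$vertices, m$vertices)
  th <- 0.7
  rigid <- diag(4)
  rigid[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rigid[1:3, 4] <- c(3, -2, 9)
  expect_lt(abs(mesh_volume(apply_affine(m, rigid)) - mesh_volume(m)), 1e-9)
  expect_equal(mesh_volume(apply_affine(m, diag(c(2, 2, 2, 1)))), 8)
  # mirroring flips faces to keep volume positive
  expect_equal(mesh_volume(apply_affine(m, diag(c(-1, 1, 1, 1)))), 1)
  expect_error(affine_transform(matrix(0, 4, 4)),
               class = "fastsurf_invalid_transform")
})
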
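test_that("phantoms are bit-reproducible and pass label validation", {
  spec <- phantom_spec("hippocampus", sigma = 0.4, seed = 9)
  v1 <- make_phantom(spec)
  v2 <- make_phantom(spec)
  expect_identical(v1$data, v2$data)
  expect_identical(v1$affine, v2$affine)
  for (seed in 1:4) {
    v <- make_phantom(phantom_spec("hippocampus", sigma = 0.5, seed = seed))
    expect_silent(validate_label_volume(v))
    expect_true(all(v$data %in% c(0L, 1L)))
  }
})

test_that("the hippocampus phantom lands in the anatomical regime", {
  vol <- make_phantom(phantom_spec("hippocampus"))
  n_slices <- sum(apply(vol$data > 0, 3, any))
  expect_true(n_slices >= 18 && n_slices <= 22)    # ~20 slices at 1.2 mm
  v <- attr(vol, "analytic_volume")
  expect_true(v > 2000 && v < 3500)                # 2-3.5 cm^3
})

test_that("voxel counts match analytic volumes for solids", {
  vol <- make_phantom(phantom_spec("sphere", radius = 8, spacing = c(1, 1, 1)))
  vox <- sum(vol$data)
  expect_lt(abs(vox - 4 / 3 * pi * 512) / (4 / 3 * pi * 512), 0.02)
})

test_that("analytic metadata matches mesh volume at both resolutions", {
  for (kind in c("sphere", "ellipsoid", "cylinder", "box", "hippocampus")) {
    full <- make_phantom(phantom_spec(kind))
    err_full <- abs(mesh_volume(mesh_from_labels(full)) /
                    attr(full, "analytic_volume") - 1)
    expect_lt(err_full, 0.05)
    half <- make_phantom(phantom_spec(kind, spacing = c(0.5, 0.5, 0.6)))
    err_half <- abs(mesh_volume(mesh_from_labels(half)) /
                    attr(half, "analytic_volume") - 1)
    expect_lt(err_half, 0.02)
  }
})

test_that("atrophy scaling changes volume by the requested fraction", {
  spec <- phantom_spec("hippocampus", atrophy_fraction = 0.05)
  pair <- make_longitudinal_pair(spec)
  ratio <- sum(pair$followup$data) / sum(pair$baseline$data)
  expect_lt(abs(ratio - 0.95), 0.005)
  # mesh-based recovery at finer rasterization: within one percentage point
  spec_f <- phantom_spec("hippocampus", atrophy_fraction = 0.05,
                         spacing = c(0.5, 0.5, 0.5))
  pair_f <- make_longitudinal_pair(spec_f)
  p <- pvc(mesh_volume(mesh_from_labels(pair_f$baseline)),
           mesh_volume(mesh_from_labels(pair_f$followup)))
  expect_lt(abs(p - 5), 1)
})

test_that("back-to-back pairs behave like independent re-delineations", {
  # sigma = 0: both members identical
  pair0 <- make_btb_pair(phantom_spec("hippocampus", sigma = 0))
  expect_identical(pair0$a$data, pair0$b$data)
  # sigma = 0.5 mm: overlap degraded but still high
  pair <- make_btb_pair(phantom_spec("hippocampus", sigma = 0.5, seed = 11))
  expect_false(identical(pair$a$data, pair$b$data))
  j <- jaccard_grid(mesh_from_labels(pair$a), mesh_from_labels(pair$b),
                    0.5)$jaccard
  expect_gt(j, 0.7)
  expect_lt(j, 1.0)
  # mean-zero jitter: underlying volume preserved within rasterization error
  va <- sum(pair$a$data)
  vb <- sum(pair$b$data)
  expect_lt(abs(va - vb) / va, 0.05)
  # larger sigma degrades the pairwise overlap
  pair2 <- make_btb_pair(phantom_spec("hippocampus", sigma = 0.25, seed = 11))
  j2 <- jaccard_grid(mesh_from_labels(pair2$a), mesh_from_labels(pair2$b),
                     0.5)$jaccard
  expect_gt(j2, j)
})

test_that("phantom specs validate sizes and survive JSON round-trips", {
  expect_error(phantom_spec("sphere", radius = -1),
               class = "fastsurf_spec_error")
  expect_error(phantom_spec("hippocampus", atrophy_fraction = 0.8),
               class = "fastsurf_spec_error")
  spec <- phantom_spec("hippocampus", sigma = 0.3, seed = 21,
                       atrophy_fraction = 0.04)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_identical(make_phantom(back)$data, make_phantom(spec)$data)
})
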
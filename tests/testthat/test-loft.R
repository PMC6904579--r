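# Lofting: watertightness, similarity scaling, mesh convergence, and
# agreement with the brute-force voxel oracle.

test_that("every bundled preset lofts to a watertight positive solid", {
  for (sp in species_presets()$species) {
    m <- loft_scale(preset_params(sp), 32, 32)
    expect_true(mesh_is_watertight(m), label = sp)
    expect_gt(mesh_volume(m), 0)
    expect_gt(min(chitonarmor:::triangle_areas(m)), 1e-12)
  }
  m <- loft_scale(prototype_params(10), 32, 32)
  expect_true(mesh_is_watertight(m))
})

test_that("uniform scaling multiplies volume by s^3 and preserves angles", {
  p <- scale_params()
  m1 <- loft_scale(p, 40, 40)
  m2 <- loft_scale(scale_params_scale(p, 2), 40, 40)
  expect_equal(mesh_volume(m2), 8 * mesh_volume(m1), tolerance = 1e-6)
  r1 <- measure_scale(m1); r2 <- measure_scale(m2)
  expect_equal(r2$alpha, r1$alpha, tolerance = 1e-4)
  expect_equal(r2$beta, r1$beta, tolerance = 1e-4)
  expect_equal(r2$V, 8 * r1$V, tolerance = 1e-6)
  expect_equal(r2$A_total, 4 * r1$A_total, tolerance = 1e-3)
})

test_that("mesh volume and descriptors converge when doubling resolution", {
  p <- scale_params()
  m1 <- loft_scale(p, 48, 48)
  m2 <- loft_scale(p, 96, 96)
  expect_lt(abs(mesh_volume(m2) - mesh_volume(m1)) / mesh_volume(m2), 0.005)
  r1 <- measure_scale(m1); r2 <- measure_scale(m2)
  expect_lt(abs(r2$A1 - r1$A1) / r2$A1, 0.01)
  expect_lt(abs(r2$A2 - r1$A2) / r2$A2, 0.01)
})

test_that("lofted volume agrees with the voxel ray-parity oracle within 1%", {
  m <- loft_scale(scale_params(), 48, 48)
  vox <- voxel_volume_centroid(m, nx = 110, ny = 170)
  expect_lt(abs(vox$volume - mesh_volume(m)) / vox$volume, 0.01)
})

test_that("loft input validation and degenerate-profile errors are raised", {
  expect_error(loft_scale(scale_params(), 3, 40),
               class = "chiton_validation_error")
  expect_error(loft_scale(scale_params(), 40, 6),
               class = "chiton_validation_error")
})
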
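# Mesh kernel: divergence-theorem volume/centroid, watertightness,
# cross-sections, proximity queries.

test_that("volume, centroid and sections are exact on an analytic box", {
  bx <- generate_fixtures("box", w = 2, l = 3, h = 0.5)
  expect_true(mesh_is_watertight(bx))
  expect_equal(mesh_volume(bx), 3, tolerance = 1e-12)
  expect_equal(mesh_centroid(bx), c(0, 0, 0.25), tolerance = 1e-12)
  expect_equal(chitonarmor:::mesh_section_area(bx, 3, 0.2), 6, tolerance = 1e-12)
  expect_equal(chitonarmor:::mesh_section_area(bx, 2, 0.4), 1, tolerance = 1e-12)
})

test_that("rigid transforms preserve volume and move the centroid rigidly", {
  bx <- generate_fixtures("box")
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(1, -2, 3)
  bt <- mesh_transform(bx, R, tr)
  expect_equal(mesh_volume(bt), mesh_volume(bx), tolerance = 1e-12)
  expect_equal(mesh_centroid(bt), as.vector(R %*% mesh_centroid(bx)) + tr,
               tolerance = 1e-12)
})

test_that("mesh-to-mesh distance matches the analytic gap of two cubes", {
  a <- generate_fixtures("box")
  b <- mesh_transform(generate_fixtures("box"), translation = c(0, 2, 0))
  md <- mesh_min_distance(a, b, cutoff = 5)
  expect_equal(md$distance, 1, tolerance = 1e-9)
  # witnesses realise the distance
  expect_equal(sqrt(sum((md$p1 - md$p2)^2)), md$distance, tolerance = 1e-9)
  # beyond the cutoff the query reports Inf
  far <- mesh_transform(generate_fixtures("box"), translation = c(0, 40, 0))
  expect_identical(mesh_min_distance(a, far, cutoff = 5)$distance, Inf)
})

test_that("face-index validation rejects malformed meshes", {
  expect_error(scale_mesh(matrix(0, 3, 3), matrix(c(1, 2, 4), 1)),
               class = "chiton_validation_error")
})
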
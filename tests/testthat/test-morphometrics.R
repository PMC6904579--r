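# Morphometrics: analytic fixtures, round-trip recovery, equivariance,
# additivity identities, and oracle agreement.

test_that("a unit cube measures as a degenerate prism with exact descriptors", {
  rec <- measure_scale(generate_fixtures("box"))
  expect_equal(rec$W, 1, tolerance = 1e-6)
  expect_equal(rec$L, 1, tolerance = 1e-6)
  expect_equal(rec$H, 1, tolerance = 1e-9)
  expect_equal(rec$V, 1, tolerance = 1e-9)
  expect_equal(rec$A_total, 1, tolerance = 5e-3)
  expect_equal(rec$centroid, c(0, 0, 0.5), tolerance = 1e-9)
  expect_true(rec$flags[["degenerate"]])
  expect_equal(rec$alpha, 180)
  expect_equal(rec$h1, rec$H)
})

test_that("an inclined prism recovers its inclination angle", {
  m <- generate_fixtures("inclined_prism", beta = 30)
  rec <- measure_scale(m)
  expect_equal(rec$beta, 30, tolerance = 0.5)
  expect_true(rec$flags[["degenerate"]])
  # transverse contour of the sheared prism is a parallelogram: area L*H
  pc <- project_contours(m, n_scan = 400)
  expect_equal(pc$transverse$area, 1, tolerance = 5e-3)
})

test_that("measuring the generated default scale recovers its parameters", {
  p <- scale_params()
  rec <- measure_scale(loft_scale(p, 64, 64))
  ang <- nominal_angles(p)
  expect_equal(rec$alpha, unname(ang["alpha"]), tolerance = 2)
  expect_equal(rec$beta, unname(ang["beta"]), tolerance = 2)
  expect_equal(rec$W, p$width, tolerance = 0.02 * p$width)
  expect_equal(rec$L, p$length, tolerance = 0.02 * p$length)
  expect_equal(rec$H, p$height, tolerance = 0.02 * p$height)
  expect_lt(abs(rec$h1 - p$h1) / p$h1, 0.05)
})

test_that("descriptors are equivariant under uniform scaling", {
  p <- scale_params()
  r1 <- measure_scale(loft_scale(p, 40, 40))
  r2 <- measure_scale(loft_scale(scale_params_scale(p, 3), 40, 40))
  expect_equal(r2$L, 3 * r1$L, tolerance = 1e-6)
  expect_equal(r2$h1, 3 * r1$h1, tolerance = 0.01)
  expect_equal(r2$A1, 9 * r1$A1, tolerance = 1e-3)
  expect_equal(r2$V, 27 * r1$V, tolerance = 1e-6)
  expect_equal(r2$ratios, r1$ratios, tolerance = 1e-3)
})

test_that("additivity identities hold exactly by construction", {
  for (sp in c("Rhyssoplax canariensis", "Ischnochiton australis")) {
    rec <- measure_scale(loft_scale(preset_params(sp), 40, 40))
    expect_identical(rec$H, rec$h1 + rec$h2)
    expect_identical(rec$A_total, rec$A1 + rec$A2)
  }
})

test_that("silhouette areas agree with the raster oracle within 0.5%", {
  m <- loft_scale(scale_params(), 48, 48)
  pc <- project_contours(m, n_scan = 500)
  rt <- raster_silhouette_area(m, "transverse", n = 300)
  rb <- raster_silhouette_area(m, "bottom", n = 300)
  expect_lt(abs(pc$transverse$area - rt) / rt, 0.005)
  expect_lt(abs(pc$bottom$area - rb) / rb, 0.005)
})

test_that("volume and centroid agree with the voxel oracle", {
  m <- loft_scale(scale_params(), 48, 48)
  rec <- measure_scale(m)
  vox <- voxel_volume_centroid(m, nx = 110, ny = 170)
  expect_lt(abs(rec$V - vox$volume) / vox$volume, 0.01)
  expect_lt(sqrt(sum((rec$centroid - vox$centroid)^2)), 0.01 * rec$L)
})

test_that("the basal centre-of-mass check accepts scales and rejects a top-heavy overhanging solid", {
  rec <- measure_scale(loft_scale(scale_params(), 40, 40))
  expect_true(basal_com_check(rec))
  mush <- generate_fixtures("mushroom")
  expect_false(basal_com_check(measure_scale(mush)))
})

test_that("the doubly-curved preset raises the multi-inflection flag", {
  rec <- measure_scale(loft_scale(preset_params("Lepidozona mertensii"), 64, 64))
  expect_true(rec$flags[["multi_inflection"]])
  rec1 <- measure_scale(loft_scale(scale_params(), 64, 64))
  expect_false(rec1$flags[["multi_inflection"]])
})

test_that("canonical re-posing undoes a rigid displacement of an external mesh", {
  m <- loft_scale(scale_params(), 40, 40)
  th <- 25 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- mesh_transform(m, R, c(3, -1, 0.4))
  moved$provenance <- "external"
  back <- canonical_pose(moved)
  r0 <- measure_scale(m)
  r1 <- measure_scale(back)
  expect_equal(r1$L, r0$L, tolerance = 0.02)
  expect_equal(r1$alpha, r0$alpha, tolerance = 2)
  expect_equal(r1$V, r0$V, tolerance = 1e-6)
})
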
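# Principal curves, markers, and the medial spine.

test_that("the principal curves carry exactly 20 labelled markers", {
  cv <- build_principal_curves(scale_params())
  expect_equal(nrow(cv$markers), 20)
  expect_equal(sum(startsWith(rownames(cv$markers), "base_")), 8)
  expect_equal(sum(startsWith(rownames(cv$markers), "yz_")), 7)
  expect_equal(sum(startsWith(rownames(cv$markers), "xz_")), 5)
})

test_that("the base contour is closed, simple, and attains the W/L extents", {
  p <- scale_params(width = 0.6, length = 1.2, fillet_front = 0.05,
                    fillet_side = 0.06)
  cv <- build_principal_curves(p)
  bc <- cv$base_contour
  expect_equal(max(bc[, 1]) - min(bc[, 1]), 0.6, tolerance = 1e-3)
  expect_equal(max(bc[, 2]) - min(bc[, 2]), 1.2, tolerance = 1e-3)
  # simple: no self intersections of the closed polyline
  expect_false(chitonarmor:::polyline_self_intersects(rbind(bc, bc[1, ])))
})

test_that("a vertical-extrusion parameter set yields a vertical spine of length H", {
  # symmetric markers, no setbacks: the profile degenerates to a symmetric
  # slab and the medial spine must be the vertical segment (0,0) -> (0,H)
  p <- scale_params(width = 0.5, length = 1, fillet_front = 0.02,
                    fillet_side = 0.02,
                    h1 = 0.3, setback_post = 1e-9, setback_ant = 1e-9,
                    h1_ant = 0.3, apex_y = -0.25, height = 0.8,
                    tip_y = 0, tip_z = 0.8,
                    under_y = 0.25, under_z = 0.79,
                    xz_w_mid = 0.8, xz_t_mid = 0.5, xz_w_tip = 0.5)
  sp <- extract_spine(build_principal_curves(p))
  expect_equal(sp$points[1, ], c(0, 0), tolerance = 1e-6)
  expect_equal(sp$points[nrow(sp$points), 2], 0.8, tolerance = 0.02)
  expect_lt(max(abs(sp$points[, 1])), 0.02)
  expect_equal(sp$arclength, 0.8, tolerance = 0.05)
})

test_that("spine endpoints match the medial endpoints of the YZ profile", {
  cv <- build_principal_curves(scale_params())
  sp <- extract_spine(cv, n = 600)
  br <- chitonarmor:::yz_branches(cv)
  base_mid <- (br$back[1, ] + br$front[1, ]) / 2
  tip <- br$back[nrow(br$back), ]
  expect_equal(sp$points[1, ], unname(base_mid), tolerance = 1e-6)
  expect_equal(sp$points[nrow(sp$points), ], unname(tip), tolerance = 1e-6)
  # arc length of the curved spine exceeds its chord
  chord <- sqrt(sum((sp$points[nrow(sp$points), ] - sp$points[1, ])^2))
  expect_gt(sp$arclength, chord)
})

test_that("the doubly-curved species profile changes bending sign twice", {
  p <- preset_params("Lepidozona mertensii")
  cv <- build_principal_curves(p)
  br <- chitonarmor:::yz_branches(cv)
  pc <- chitonarmor:::polyline_curvature(br$back, n_resample = 300)
  ks <- pc$curvature
  kref <- max(abs(ks))
  sgn <- sign(ks)
  sgn[abs(ks) < 0.15 * kref] <- 0
  r <- rle(sgn)
  strong <- r$values[r$lengths >= 8 & r$values != 0]
  # posterior profile bends one way, then the other: at least one sign
  # alternation among the sustained bending runs
  expect_gte(length(unique(strong)), 2)
})
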
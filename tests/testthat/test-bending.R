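# Rigid-scale bending kinematics: identity at zero curvature, convex
# freedom, analytic small-rotation check, contact monotonicity, and the
# bisection bracket for the onset curvature.

small_asm <- function(rows = 4, cols = 4, res = 24)
  tile_uniform(assembly_spec(rows = rows, cols = cols,
                             resolution = c(res, res)))

test_that("zero curvature is the identity on every scale", {
  asm <- small_asm()
  st <- bend(asm, 30, 0)
  for (p in st$placements) {
    expect_equal(p$bent_rotation, diag(3), tolerance = 1e-12)
    expect_equal(p$bent_translation, c(0, 0, 0), tolerance = 1e-12)
  }
})

test_that("convex bending stays contact-free far beyond the concave onset", {
  # the crowns separate under convex bending; only the embedded bases
  # (substrate-filled in the physical panel) could ever meet, and that
  # happens at several times the concave interlocking curvature
  asm <- small_asm()
  k_star <- onset_curvature(asm, 0)$kappa_star
  for (phi in c(0, 60, 90)) {
    for (k in c(-k_star, -2 * k_star, -0.02)) {
      cg <- detect_contacts(bend(asm, phi, k))
      expect_equal(nrow(cg), 0)
    }
  }
})

test_that("per-scale rotation matches the analytic cylinder map at small curvature", {
  asm <- small_asm()
  kappa <- 0.002
  st <- bend(asm, 0, kappa)
  for (p in st$placements) {
    s <- p$translation[2]
    ang <- acos(pmin(1, (sum(diag(p$bent_rotation)) - 1) / 2))
    expect_equal(ang, abs(s * kappa), tolerance = 0.01 * max(abs(s * kappa), 1e-9))
  }
  # midsurface arc lengths are preserved (isometric wrapping)
  p1 <- st$placements[[1]]; p2 <- st$placements[[5]]
  z_mid <- asm$spec$h_sub / 2
  w1 <- p1$bent_rotation %*% c(p1$translation[1:2], z_mid) + p1$bent_translation
  w2 <- p2$bent_rotation %*% c(p2$translation[1:2], z_mid) + p2$bent_translation
  rho <- 1 / kappa
  chord <- sqrt(sum((w1 - w2)^2))
  ds <- abs(p1$translation[2] - p2$translation[2])
  dt <- abs(p1$translation[1] - p2$translation[1])
  arc_chord <- sqrt((2 * rho * sin(ds / (2 * rho)))^2 + dt^2)
  expect_equal(chord, arc_chord, tolerance = 1e-9)
})

test_that("two separated cubes register contact only within the tolerance", {
  a <- generate_fixtures("box")
  b <- mesh_transform(generate_fixtures("box"), translation = c(0, 2, 0))
  asm <- small_asm(rows = 1, cols = 1, res = 16)
  st <- bend(asm, 0, 0)
  st$placements <- list(
    list(id = 1L, rotation = diag(3), translation = c(0, 0, 0), size = 1,
         bent_rotation = diag(3), bent_translation = c(0, 0, 0)),
    list(id = 2L, rotation = diag(3), translation = c(0, 2, 0), size = 1,
         bent_rotation = diag(3), bent_translation = c(0, 0, 0)))
  st$assembly$template <- generate_fixtures("box")
  st$assembly$lattice <- NULL
  expect_equal(nrow(detect_contacts(st, tolerance = 0.1)), 0)
  cg <- detect_contacts(st, tolerance = 1.01)
  expect_equal(nrow(cg), 1)
  expect_equal(cg$class, "other")
})

test_that("contact count grows monotonically with concave curvature", {
  asm <- small_asm(rows = 5, cols = 5)
  on <- onset_curvature(asm, 0)
  expect_true(is.finite(on$kappa_star))
  ks <- seq(on$kappa_star, 2 * on$kappa_star, length.out = 4)
  counts <- vapply(ks, function(k) nrow(detect_contacts(bend(asm, 0, k))), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("the onset bisection brackets the first contact", {
  asm <- small_asm(rows = 5, cols = 5)
  on <- onset_curvature(asm, 0, tol_kappa = 1e-4)
  ids <- interior_ids(asm)
  below <- detect_contacts(bend(asm, 0, on$kappa_star - 2e-4), ids = ids)
  above <- detect_contacts(bend(asm, 0, on$kappa_star + 2e-4), ids = ids)
  expect_equal(nrow(below), 0)
  expect_gt(nrow(above), 0)
})

test_that("well-separated tiny scales report the no-interlocking sentinel", {
  p <- scale_params_scale(prototype_params(1), 1)   # L = 1 mm scales
  spec <- assembly_spec(params = p, scale_length = 1, spacing = 0.9,
                        rows = 3, cols = 3, resolution = c(12, 12))
  asm <- tile_uniform(spec)
  # move the sites far apart: L much smaller than the pitch
  for (k in seq_along(asm$placements))
    asm$placements[[k]]$translation <- asm$placements[[k]]$translation * 8
  on <- onset_curvature(asm, 0)
  expect_true(is.na(on$kappa_star))
  expect_equal(on$first_contact_class, "no interlocking")
})
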
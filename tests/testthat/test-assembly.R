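# Armor assembly: lattice geometry, spacing, substrate, gradient fans,
# curved hosts, reference-state disjointness and dorsal coverage.

test_that("uniform tiling reproduces the prescribed base gap exactly", {
  spec <- assembly_spec(rows = 3, cols = 3, resolution = c(16, 16))
  asm <- tile_uniform(spec)
  bc <- chitonarmor:::base_contour(spec$params, 256)
  e <- asm$lattice[asm$lattice$class == "diagonal", ][1, ]
  c1 <- asm$placements[[e$a]]$translation[1:2]
  c2 <- asm$placements[[e$b]]$translation[1:2]
  gap <- polygon_min_distance(sweep(bc, 2, c1, `+`), sweep(bc, 2, c2, `+`))
  expect_equal(gap, spec$d, tolerance = 1e-6)
  expect_equal(gap / spec$L, 0.05, tolerance = 1e-6)
})

test_that("a 1x1 grid places a single scale at the origin", {
  asm <- tile_uniform(assembly_spec(rows = 1, cols = 1,
                                    resolution = c(16, 16)))
  expect_length(asm$placements, 1)
  expect_equal(asm$placements[[1]]$translation, c(0, 0, 0))
})

test_that("interior lattice sites have exactly four diagonal neighbours", {
  asm <- tile_uniform(assembly_spec(rows = 5, cols = 5,
                                    resolution = c(16, 16)))
  ids <- interior_ids(asm)
  expect_gt(length(ids), 0)
  for (id in ids) {
    nd <- sum(asm$lattice$class == "diagonal" &
                (asm$lattice$a == id | asm$lattice$b == id))
    expect_equal(nd, 4)
  }
})

test_that("the substrate slab is watertight with the prescribed thickness", {
  asm <- tile_uniform(assembly_spec(rows = 3, cols = 3,
                                    resolution = c(16, 16)))
  sub <- build_substrate(asm)
  expect_true(mesh_is_watertight(sub$mesh))
  expect_equal(sub$thickness, 4.1, tolerance = 1e-12)
  zr <- range(sub$mesh$vertices[, 3])
  expect_equal(zr[2] - zr[1], 4.1, tolerance = 1e-9)
})

test_that("substrate volume equals slab minus embedded bases within 1%", {
  asm <- tile_uniform(assembly_spec(rows = 3, cols = 3,
                                    resolution = c(32, 32)))
  sub <- build_substrate(asm)
  vox <- voxel_volume_centroid(asm$template, nx = 100, ny = 150)
  # independent estimate of the embedded volume: voxel columns clipped at
  # the substrate top
  m <- asm$template
  clip <- m
  keepz <- pmin(clip$vertices[, 3], sub$thickness)
  clip$vertices[, 3] <- keepz
  vox_emb <- voxel_volume_centroid(clip, nx = 100, ny = 150)$volume
  slab <- sub$footprint_area * sub$thickness
  expect_lt(abs(sub$volume - (slab - 9 * vox_emb)) / sub$volume, 0.01)
})

test_that("an empty placement list yields a plain slab", {
  asm <- tile_uniform(assembly_spec(rows = 1, cols = 1,
                                    resolution = c(16, 16)))
  asm$placements <- list()
  sub <- build_substrate(asm)
  expect_true(mesh_is_watertight(sub$mesh))
  expect_equal(sub$volume, sub$footprint_area * sub$thickness,
               tolerance = 1e-9)
  expect_equal(mesh_volume(sub$mesh), sub$volume, tolerance = 1e-9)
})

test_that("gradient fans with zero divergence reduce to the uniform lattice", {
  pit <- chitonarmor:::lattice_pitch(assembly_spec(rows = 4, cols = 4))
  e1 <- c(pit[["sx"]] / 2, pit[["sy"]] / 2)
  e2 <- c(-pit[["sx"]] / 2, pit[["sy"]] / 2)
  sp_perp <- abs(e1[1] * e2[2] - e1[2] * e2[1]) / sqrt(sum(e1^2))
  fan <- list(origin_a = c(0, 0), angle_a = atan2(e1[2], e1[1]) * 180 / pi,
              dangle_a = 0, spacing_a = sp_perp,
              origin_b = c(0, 0), angle_b = atan2(e2[2], e2[1]) * 180 / pi,
              dangle_b = 0, spacing_b = sp_perp)
  gs <- assembly_spec("gradient_fan", rows = 4, cols = 4, fan = fan,
                      resolution = c(16, 16))
  g <- tile_gradient_fan(gs)
  sizes <- vapply(g$placements, function(p) p$size, 0)
  expect_true(all(abs(sizes - 1) < 1e-9))
  # all cell centres lie on the uniform diamond lattice generated by the
  # two line families
  uo <- tile_uniform(assembly_spec(rows = 9, cols = 9, resolution = c(16, 16)))
  upts <- do.call(rbind, lapply(uo$placements, function(p) p$translation[1:2]))
  for (p in g$placements) {
    ctr <- p$translation[1:2]
    rel <- sweep(upts, 2, ctr)
    dmin <- sqrt(min(rowSums(sweep(rel, 2, colMeans(rel) * 0)^2)))
    # relative lattice positions are congruent modulo the generators
    e1 <- c(pit["sx"] / 2, pit["sy"] / 2); e2 <- c(-pit["sx"] / 2, pit["sy"] / 2)
    A <- cbind(e1, e2)
    uv <- solve(A, ctr - g$placements[[1]]$translation[1:2])
    expect_equal(uv, round(uv), tolerance = 1e-6)
  }
})

test_that("fan-tiled scale sizes shrink strictly toward the distal margin", {
  gs <- assembly_spec("gradient_fan", rows = 5, cols = 4,
                      resolution = c(16, 16))
  g <- tile_gradient_fan(gs)
  sizes <- vapply(g$placements, function(p) p$size, 0)
  ii <- vapply(g$placements, function(p) p$i, 0L)
  jj <- vapply(g$placements, function(p) as.numeric(p$j), 0)
  for (i in unique(ii)) {
    s <- sizes[ii == i][order(jj[ii == i])]
    expect_true(all(diff(s) < 0))
  }
})

test_that("fan cell areas match the polygon-clipping oracle", {
  gs <- assembly_spec("gradient_fan", rows = 3, cols = 3,
                      resolution = c(16, 16))
  g <- tile_gradient_fan(gs)
  fan <- chitonarmor:::default_gradient_fan(gs)
  fa <- list(origin = fan$origin_a, angle = fan$angle_a, dangle = fan$dangle_a,
             spacing = 0)
  fb <- list(origin = fan$origin_b, angle = fan$angle_b, dangle = fan$dangle_b,
             spacing = 0)
  big <- cbind(c(-900, 900, 900, -900), c(-900, -900, 900, 900))
  # oracle: clip a large rectangle by the four pencil half-planes bounding
  # the first cell, and find its area among the stored cell areas
  la0 <- chitonarmor:::fan_line(fa, 0); la1 <- chitonarmor:::fan_line(fa, 1)
  lb0 <- chitonarmor:::fan_line(fb, 0); lb1 <- chitonarmor:::fan_line(fb, 1)
  ctr <- (chitonarmor:::line_intersect(la0, lb0) +
          chitonarmor:::line_intersect(la1, lb1) +
          chitonarmor:::line_intersect(la0, lb1) +
          chitonarmor:::line_intersect(la1, lb0)) / 4
  poly <- big
  for (ln in list(la0, la1, lb0, lb1)) {
    nrm <- c(-ln$u[2], ln$u[1])
    b <- sum(nrm * ln$p)
    if (sum(nrm * ctr) < b) { nrm <- -nrm; b <- -b }
    poly <- clip_convex(poly, nrm, b)
  }
  oracle_area <- shoelace(poly)
  areas <- vapply(g$placements, function(q) q$cell_area, 0)
  expect_true(any(abs(areas - oracle_area) / oracle_area < 1e-9))
})

test_that("plane hosts reproduce the flat uniform tiling exactly", {
  po <- tile_on_surface(assembly_spec("on_surface", rows = 2, cols = 2,
                                      host = list(type = "plane"),
                                      resolution = c(16, 16)))
  uo <- tile_uniform(assembly_spec(rows = 2, cols = 2, resolution = c(16, 16)))
  for (k in seq_along(po$placements)) {
    expect_equal(po$placements[[k]]$translation,
                 uo$placements[[k]]$translation, tolerance = 1e-9)
    expect_equal(po$placements[[k]]$rotation, uo$placements[[k]]$rotation,
                 tolerance = 1e-9)
  }
})

test_that("cylinder hosts align every scale with the analytic surface normal", {
  R <- 60
  co <- tile_on_surface(assembly_spec("on_surface", rows = 3, cols = 3,
                                      host = list(type = "cylinder", radius = R),
                                      resolution = c(16, 16)))
  for (p in co$placements) {
    v <- p$translation
    n_true <- c(0, v[2] / R, (v[3] + R) / R)
    ang <- acos(min(1, sum(p$rotation[, 3] * n_true))) * 180 / pi
    expect_lt(ang, 0.1)
  }
  # neighbouring scales remain disjoint on the curved host
  e <- co$lattice[co$lattice$class == "diagonal", ][1, ]
  md <- mesh_min_distance(placed_scale_mesh(co, e$a),
                          placed_scale_mesh(co, e$b), cutoff = 5)
  expect_gt(md$distance, 0)
})

test_that("size factors shrink monotonically with sphere-cap curvature", {
  sizes <- vapply(c(200, 100, 50, 15), function(R) {
    so <- tile_on_surface(assembly_spec("on_surface", rows = 2, cols = 2,
                                        host = list(type = "sphere_cap",
                                                    radius = R),
                                        resolution = c(16, 16)))
    so$placements[[1]]$size
  }, 0)
  expect_true(all(diff(sizes) <= 0))
  expect_lt(sizes[4], 1)
})

test_that("the reference uniform assembly has disjoint scales", {
  asm <- tile_uniform(assembly_spec(rows = 4, cols = 4,
                                    resolution = c(28, 28)))
  cg <- detect_contacts(bend(asm, 0, 0))
  expect_equal(nrow(cg), 0)
  for (cl in c("hook_row", "diagonal", "same_row")) {
    e <- asm$lattice[asm$lattice$class == cl, ][1, ]
    md <- mesh_min_distance(placed_scale_mesh(asm, e$a),
                            placed_scale_mesh(asm, e$b), cutoff = 5)
    expect_gt(md$distance, 0.02)
  }
})

test_that("dorsal projection of the scale union covers the interior footprint", {
  p <- scale_params_scale(preset_params("Rhyssoplax canariensis"),
                          10 / preset_params("Rhyssoplax canariensis")$length)
  asm <- tile_uniform(assembly_spec(params = p, scale_length = 10,
                                    rows = 5, cols = 5,
                                    resolution = c(24, 24)))
  cov <- coverage_fraction(asm, n_grid = 70)
  expect_gte(cov, 0.99)
})
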
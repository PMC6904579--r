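# Parameter schema: counts, validation conditions, similarity scaling.

test_that("the free-parameter schema has 17 names in the documented groups", {
  nm <- scale_param_names()
  expect_named(nm, c("base", "yz", "xz"))
  expect_length(nm$base, 4)
  expect_length(nm$yz, 10)
  expect_length(nm$xz, 3)
  expect_length(unlist(nm), 17)
  expect_false(anyDuplicated(unlist(nm)) > 0)
  # every schema name is an accepted constructor argument
  expect_true(all(unlist(nm) %in% names(formals(scale_params))))
})

test_that("validation rejects bad parameters with named conditions", {
  expect_error(scale_params(width = -1), class = "chiton_validation_error")
  expect_error(scale_params(h1 = 0.7, height = 0.6),
               class = "chiton_validation_error")
  expect_error(scale_params(fillet_front = 0.5),
               class = "chiton_validation_error")
  e <- tryCatch(scale_params(width = -1), chiton_validation_error = identity)
  expect_identical(e$field, "width")
  # non-overlapping geometry: a drooping hook whose underside falls
  err <- tryCatch(scale_params(h1_ant = 0.4, under_z = 0.25, tip_z = 0.22),
                  chiton_validation_error = identity)
  expect_match(conditionMessage(err), "non-overlapping")
})

test_that("nominal angles are invariant under uniform scaling", {
  p <- scale_params()
  for (s in c(0.25, 3)) {
    q <- scale_params_scale(p, s)
    expect_equal(nominal_angles(q), nominal_angles(p), tolerance = 1e-6)
    expect_equal(q$length, s * p$length)
  }
})

test_that("nominal and overlap-capable angles hold for every preset", {
  for (sp in species_presets()$species) {
    ang <- nominal_angles(preset_params(sp))
    expect_lt(ang["alpha"] + ang["beta"], 180)
    expect_gte(ang["beta"], 0)
    expect_lt(ang["beta"], 90)
  }
})
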
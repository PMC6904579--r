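# Species preset registry: all ten species generate, measure, and satisfy
# their recorded descriptor ranges.

test_that("the registry lists ten species across the two families", {
  tab <- species_presets()
  expect_equal(nrow(tab), 10)
  expect_setequal(unique(tab$family), c("Chitonidae", "Ischnochitonidae"))
  expect_equal(sum(tab$family == "Ischnochitonidae"), 5)
})

test_that("every species preset passes its recorded morphometric checks", {
  t0 <- Sys.time()
  for (sp in species_presets()$species) {
    rec <- measure_scale(loft_scale(preset_params(sp), 48, 48))
    expect_true(isTRUE(preset_check(sp, rec)),
                label = paste(sp, ":", paste(preset_check(sp, rec),
                                             collapse = ", ")))
  }
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
})

test_that("species volumes span the reported interspecific extremes", {
  v <- vapply(species_presets()$species, function(sp)
    measure_scale(loft_scale(preset_params(sp), 32, 32))$V, 0)
  expect_equal(unname(v["Lepidozona mertensii"]), 0.005, tolerance = 0.25)
  expect_equal(unname(v["Rhyssoplax polita"]), 0.1, tolerance = 0.25)
  expect_lt(min(v), 0.008)
  expect_gt(max(v), 0.07)
})

test_that("unknown species names are rejected", {
  expect_error(preset_params("Chiton imaginarius"),
               class = "chiton_validation_error")
})
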
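# Species preset registry: parameter sets for the dorsal girdle scales of
# ten chiton species from two families (Ischnochitonidae, Chitonidae),
# calibrated so the measured morphometrics of the generated meshes fall in
# the descriptor ranges reported for each species (imbrication angle alpha
# about 90 degrees in I. australis and L. mertensii up to about 130 in
# I. lentiginosus; inclination angle beta about 10 degrees in C. cumingsii
# up to about 60 in I. australis; basal fraction h1/H about 0.5 in
# C. cumingsii and I. contractus versus 0.3-0.4 elsewhere; volumes from
# about 0.005 mm^3 in L. mertensii to about 0.1 mm^3 in R. polita).
# L. mertensii carries the doubly-curved profile (two inflection points).
#
# Each entry stores the unit-length shape (base length 1 mm) plus a size
# factor that scales the scale isotropically to its published mid-girdle
# volume.

.preset_table <- function() {
  list(
    "Rhyssoplax canariensis" = list(
      family = "Chitonidae", size = 0.425,
      shape = list(),   # the package default IS this species' shape
      ranges = list(alpha = c(110, 120), beta = c(20, 30),
                    H_L = c(0.5, 0.6), W_L = c(0.4, 0.5),
                    h1_H = c(0.3, 0.4), A1_At = c(0.3, 0.4),
                    V = c(0.005, 0.016))),
    "Rhyssoplax jugosa" = list(
      family = "Chitonidae", size = 0.744,
      shape = list(width = 0.46, h1 = 0.21, setback_post = 0.0849,
                   setback_ant = 0.075, h1_ant = 0.18, apex_y = 1.05,
                   height = 0.54, tip_y = 1.2, tip_z = 0.52,
                   under_y = 0.82, under_z = 0.37, xz_w_mid = 0.28,
                   xz_t_mid = 0.3, xz_w_tip = 0.11),
      ranges = list(alpha = c(100, 118), beta = c(18, 26),
                    H_L = c(0.5, 0.6), h1_H = c(0.3, 0.42),
                    V = c(0.02, 0.04))),
    "Rhyssoplax polita" = list(
      family = "Chitonidae", size = 1.080,
      shape = list(width = 0.5, setback_post = 0.102,
                   height = 0.57, tip_z = 0.52, under_z = 0.34,
                   xz_w_mid = 0.32, xz_t_mid = 0.3, xz_w_tip = 0.12),
      ranges = list(alpha = c(105, 120), beta = c(22, 32),
                    V = c(0.07, 0.13))),
    "Radsia barnesii" = list(
      family = "Chitonidae", size = 0.819,
      shape = list(setback_post = 0.111, setback_ant = 0.1,
                   apex_y = 1.05, height = 0.52, tip_y = 1.2,
                   tip_z = 0.49, under_z = 0.34, xz_w_mid = 0.32,
                   xz_t_mid = 0.3, xz_w_tip = 0.12),
      ranges = list(alpha = c(102, 118), beta = c(24, 34),
                    V = c(0.03, 0.05))),
    "Chiton cumingsii" = list(
      family = "Chitonidae", size = 0.789,
      shape = list(width = 0.5, h1 = 0.295, setback_post = 0.052,
                   setback_ant = 0.05, h1_ant = 0.24, apex_y = 0.95,
                   height = 0.58, tip_y = 1.05, tip_z = 0.56,
                   under_y = 0.72, under_z = 0.45, xz_w_mid = 0.32,
                   xz_t_mid = 0.35, xz_w_tip = 0.12),
      ranges = list(alpha = c(95, 115), beta = c(5, 15),
                    h1_H = c(0.44, 0.55), V = c(0.035, 0.065))),
    "Ischnochiton fruticosus" = list(
      family = "Ischnochitonidae", size = 0.646,
      shape = list(width = 0.5, setback_post = 0.168, setback_ant = 0.15,
                   height = 0.55, tip_y = 1.35, tip_z = 0.5,
                   under_y = 0.9, under_z = 0.31, xz_w_mid = 0.32,
                   xz_t_mid = 0.3, xz_w_tip = 0.12),
      ranges = list(alpha = c(95, 120), beta = c(35, 45),
                    V = c(0.014, 0.026))),
    "Ischnochiton australis" = list(
      family = "Ischnochitonidae", size = 0.722,
      shape = list(width = 0.55, h1 = 0.26, setback_post = 0.45,
                   setback_ant = 0.42, h1_ant = 0.24, apex_y = 1.25,
                   height = 0.65, tip_y = 1.55, tip_z = 0.52,
                   under_y = 1.15, under_z = 0.35, xz_w_mid = 0.3,
                   xz_t_mid = 0.35, xz_w_tip = 0.1),
      ranges = list(alpha = c(85, 100), beta = c(55, 65),
                    H_L = c(0.55, 0.75), V = c(0.02, 0.04))),
    "Ischnochiton lentiginosus" = list(
      family = "Ischnochitonidae", size = 0.579,
      shape = list(width = 0.5, setback_post = 0.14, setback_ant = 0.13,
                   h1_ant = 0.17, apex_y = 1.2, height = 0.5,
                   tip_y = 1.45, tip_z = 0.42, under_y = 0.95,
                   under_z = 0.26, xz_w_mid = 0.32, xz_t_mid = 0.3,
                   xz_w_tip = 0.12),
      ranges = list(alpha = c(120, 140), beta = c(30, 40),
                    V = c(0.01, 0.02))),
    "Ischnochiton contractus" = list(
      family = "Ischnochitonidae", size = 0.467,
      shape = list(width = 0.52, h1 = 0.27, setback_post = 0.27,
                   setback_ant = 0.25, h1_ant = 0.24, apex_y = 1.05,
                   height = 0.54, tip_y = 1.25, tip_z = 0.52,
                   under_y = 0.95, under_z = 0.4, xz_w_mid = 0.32,
                   xz_t_mid = 0.32, xz_w_tip = 0.11),
      ranges = list(alpha = c(85, 105), beta = c(40, 50),
                    h1_H = c(0.44, 0.55), V = c(0.006, 0.01))),
    "Lepidozona mertensii" = list(
      family = "Ischnochitonidae", size = 0.384,
      shape = list(width = 0.55, setback_post = 0.0728,
                   setback_ant = 0.065, h1_ant = 0.15, apex_y = -0.55,
                   height = 0.44, tip_y = 0.85, tip_z = 0.42,
                   under_y = 0.66, under_z = 0.32, xz_w_mid = 0.24,
                   xz_t_mid = 0.35, xz_w_tip = 0.1),
      ranges = list(alpha = c(85, 105), beta = c(15, 25),
                    H_L = c(0.4, 0.5), V = c(0.004, 0.007),
                    multi_inflection = TRUE))
  )
}

#' Scale parameters of the printed armor prototype
#'
#' The shape used for the flexible-armor prototype panels: scale length
#' L = 10 mm, inter-scale spacing d = 0.5 mm (d/L = 5%), and embedded
#' (inflection) height h1 = 4.1 mm, which is also the substrate thickness.
#' The prototype scale is taller and broader-crowned than the mid-girdle
#' R. canariensis morphometric scale — the printed prototype dimensions
#' (h1/L = 0.41) are not attainable with the measured girdle-scale ratios
#' (h1/L about 0.2), so the armor design carries its own calibrated shape:
#' a wide dorsal crown that leaves only a small lateral gap to the
#' diagonal neighbours while the hook rides with generous daylight over
#' the scale in front. That geometry gives the armor its
#' orientation-dependent interlocking.
#'
#' @param scale_length Base length L in mm (default 10, as printed).
#' @return A `scale_params` object.
#' @examples
#' prototype_params()$h1   # 4.1 mm: the substrate thickness
#' @export
prototype_params <- function(scale_length = 10) {
  p <- scale_params(width = 0.5, h1 = 0.41, setback_post = 0.191,
                    setback_ant = 0.17, h1_ant = 0.38,
                    apex_y = 1.05, height = 0.85, tip_y = 1.25,
                    tip_z = 0.8, under_y = 0.95, under_z = 0.58,
                    xz_w_mid = 0.62, xz_t_mid = 0.35, xz_w_tip = 0.6,
                    species = "armor prototype")
  attr(p, "crown_section") <- "slab"   # simplified printable crown
  scale_params_scale(p, scale_length)
}

#' List the bundled species presets
#'
#' @return A data frame with columns `species`, `family` and `size_factor`
#'   (the isotropic factor applied to the unit-length shape; base length in
#'   mm equals the size factor).
#' @examples
#' species_presets()
#' @export
species_presets <- function() {
  tab <- .preset_table()
  data.frame(species = names(tab),
             family = vapply(tab, function(x) x$family, ""),
             size_factor = vapply(tab, function(x) x$size, 0),
             row.names = NULL)
}

#' Scale parameters for a bundled species preset
#'
#' @param species Species name (see [species_presets()]); matched exactly.
#' @return A `scale_params` object in absolute millimetres.
#' @examples
#' p <- preset_params("Rhyssoplax canariensis")
#' @export
preset_params <- function(species) {
  tab <- .preset_table()
  if (!species %in% names(tab))
    abort_validation(paste0("unknown species preset '", species, "'"))
  e <- tab[[species]]
  p <- do.call(scale_params, c(e$shape, list(species = species)))
  scale_params_scale(p, e$size)
}

#' Expected descriptor ranges recorded for a species preset
#'
#' @param species Species name.
#' @return Named list of `c(lo, hi)` ranges (angles in degrees, ratios
#'   dimensionless, V in mm^3), plus `multi_inflection` where the species
#'   is doubly curved.
#' @export
preset_ranges <- function(species) {
  tab <- .preset_table()
  if (!species %in% names(tab))
    abort_validation(paste0("unknown species preset '", species, "'"))
  tab[[species]]$ranges
}

#' Check a morphometric record against a preset's recorded ranges
#'
#' @param species Species name.
#' @param record A `morphometrics` record measured from the preset's mesh.
#' @return TRUE if every recorded range check passes; otherwise a character
#'   vector naming the failing checks.
#' @export
preset_check <- function(species, record) {
  rg <- preset_ranges(species)
  fails <- character(0)
  getval <- function(nm) {
    if (nm %in% names(record)) return(record[[nm]])
    if (nm %in% names(record$ratios)) return(unname(record$ratios[nm]))
    NA_real_
  }
  for (nm in names(rg)) {
    if (identical(nm, "multi_inflection")) {
      if (!isTRUE(unname(record$flags["multi_inflection"])))
        fails <- c(fails, "multi_inflection")
      next
    }
    v <- getval(nm)
    if (!is.finite(v) || v < rg[[nm]][1] || v > rg[[nm]][2])
      fails <- c(fails, nm)
  }
  if (record$alpha + record$beta >= 180)
    fails <- c(fails, "overlap (alpha + beta < 180)")
  if (!basal_com_check(record))
    fails <- c(fails, "basal centre of mass")
  if (length(fails)) fails else TRUE
}
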
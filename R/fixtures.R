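# Synthetic test fixtures: simple analytic solids with known morphometrics
# (boxes, inclined prisms, a hooked prism, a top-heavy mushroom) and
# jittered preset parameters for robustness tests. All generated in code —
# no stored mesh files.

# Quad-faced box/prism builder from a closed base polygon extruded along a
# (possibly sheared) axis. Returns a watertight scale_mesh.
extrude_polygon <- function(poly, height, shear = c(0, 0)) {
  n <- nrow(poly)
  bot <- cbind(poly, 0)
  top <- cbind(poly[, 1] + shear[1] * height,
               poly[, 2] + shear[2] * height, height)
  cb <- c(colMeans(poly), 0)
  ct <- c(colMeans(poly) + shear * height, height)
  v <- rbind(bot, top, cb, ct)
  icb <- 2L * n + 1L; ict <- 2L * n + 2L
  k <- seq_len(n); k2 <- k %% n + 1L
  faces <- rbind(
    cbind(k, k2, n + k2), cbind(k, n + k2, n + k),     # side walls
    cbind(icb, k2, k),                                  # bottom fan
    cbind(ict, n + k, n + k2))                          # top fan
  m <- scale_mesh(v, faces, provenance = "external")
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Generate deterministic synthetic fixture meshes and parameters
#'
#' @param kind One of `"box"`, `"inclined_prism"`, `"hooked_prism"`,
#'   `"mushroom"`, `"noisy_preset"`.
#' @param seed Integer seed (used by `noisy_preset` only).
#' @param ... Kind-specific arguments: `box(w, l, h)`;
#'   `inclined_prism(beta, w, l, h)` with `beta` the tilt of the prism axis
#'   from the vertical, degrees; `hooked_prism(w, l, h, hook)`;
#'   `mushroom(stalk, cap)`; `noisy_preset(species, sigma)` with `sigma`
#'   the relative jitter applied to every length parameter.
#' @return A `scale_mesh`, or a `scale_params` object for `noisy_preset`.
#' @examples
#' generate_fixtures("box", w = 1, l = 1, h = 1)
#' @export
generate_fixtures <- function(kind, seed = 1, ...) {
  args <- list(...)
  g <- function(nm, def) if (!is.null(args[[nm]])) args[[nm]] else def
  switch(kind,
    box = {
      w <- g("w", 1); l <- g("l", 1); h <- g("h", 1)
      poly <- cbind(c(-w, w, w, -w) / 2, c(-l, -l, l, l) / 2)
      extrude_polygon(poly, h)
    },
    inclined_prism = {
      beta <- g("beta", 30) * pi / 180
      w <- g("w", 1); l <- g("l", 1); h <- g("h", 1)
      poly <- cbind(c(-w, w, w, -w) / 2, c(-l, -l, l, l) / 2)
      extrude_polygon(poly, h, shear = c(0, tan(beta)))
    },
    hooked_prism = {
      # a sheared prism with a forward slab on top: a crude hook with a
      # flat underside, handy for contact sanity checks
      w <- g("w", 1); l <- g("l", 1); h <- g("h", 1)
      hook <- g("hook", 0.8 * l)
      base <- extrude_polygon(cbind(c(-w, w, w, -w) / 2, c(-l, -l, l, l) / 2),
                              h)
      slab <- extrude_polygon(cbind(c(-w, w, w, -w) / 2 * 0.8,
                                    c(-l / 2, -l / 2, l / 2 + hook,
                                      l / 2 + hook)),
                              0.25 * h)
      slab <- mesh_transform(slab, translation = c(0, 0, h))
      mesh_merge(list(base, slab))
    },
    mushroom = {
      # thin stalk with a massive cap overhanging forward: the centre of
      # mass hangs beyond the supporting footprint, so the solid tips over
      # under a vertical load (the constructed counterexample to the
      # basal centre-of-mass property)
      stalk <- g("stalk", 0.3); cap <- g("cap", 1.4)
      hs <- g("h_stalk", 1); hc <- g("h_cap", 0.5)
      off <- g("cap_offset", 0.8)
      st <- extrude_polygon(cbind(c(-stalk, stalk, stalk, -stalk) / 2,
                                  c(-stalk, -stalk, stalk, stalk) / 2), hs)
      cp <- extrude_polygon(cbind(c(-cap, cap, cap, -cap) / 2,
                                  c(-cap, -cap, cap, cap) / 2), hc)
      cp <- mesh_transform(cp, translation = c(0, off, hs))
      mesh_merge(list(st, cp))
    },
    noisy_preset = {
      species <- g("species", "Rhyssoplax canariensis")
      sigma <- g("sigma", 0.02)
      p <- preset_params(species)
      old_seed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, .GlobalEnv))
      set.seed(seed)
      len_fields <- c("width", "length", "fillet_front", "fillet_side",
                      "h1", "setback_post", "setback_ant", "h1_ant",
                      "apex_y", "height", "tip_y", "tip_z",
                      "under_y", "under_z")
      for (tries in 1:50) {
        q <- p
        for (f in len_fields)
          q[[f]] <- p[[f]] * (1 + stats::rnorm(1, 0, sigma))
        ok <- tryCatch({ validate_scale_params(q); TRUE },
                       chiton_validation_error = function(e) FALSE)
        if (ok) return(q)
      }
      abort_validation("could not draw a valid jittered parameter set")
    },
    abort_validation(paste0("unknown fixture kind '", kind, "'"))
  )
}
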
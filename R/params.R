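# Parameter schema for the parametric girdle-scale model.
#
# The scale solid is scaffolded by three principal curves (BASE, YZ, XZ)
# carrying 20 geometric markers controlled by 17 free parameters:
#   BASE (4): width, length, fillet_front, fillet_side
#   YZ  (10): h1, setback_post, setback_ant, h1_ant, apex_y, height,
#             tip_y, tip_z, under_y, under_z
#   XZ   (3): xz_w_mid, xz_t_mid, xz_w_tip
# Some parameters position several markers at once (e.g. h1 fixes both
# basal-edge top corners), and the YZ/XZ sections inherit base width/length
# and apex height rather than owning them, which is why 17 parameters
# suffice for 20 markers. All lengths are millimetres.

#' Names of the free scale parameters, grouped by principal section
#'
#' @return A named list with character vectors `base`, `yz` and `xz`; the
#'   total number of names is always 17.
#' @export
scale_param_names <- function() {
  list(
    base = c("width", "length", "fillet_front", "fillet_side"),
    yz   = c("h1", "setback_post", "setback_ant", "h1_ant",
             "apex_y", "height", "tip_y", "tip_z", "under_y", "under_z"),
    xz   = c("xz_w_mid", "xz_t_mid", "xz_w_tip")
  )
}

#' Construct a validated set of scale parameters
#'
#' Builds the 17-parameter description of one girdle scale in its canonical
#' local frame: base centroid at the origin, hook curving toward `+y`
#' (the radial/overlap direction), dorsal `+z`.
#'
#' @param width,length Base diamond width (x extent) and length (y extent), mm.
#' @param fillet_front,fillet_side Corner fillet radii of the base diamond at
#'   the front/back and side vertices, mm.
#' @param h1 Height of the posterior inflection point, where the prismatic
#'   base hands over to the curved hook, mm.
#' @param setback_post,setback_ant Horizontal (+y) setback of the posterior
#'   and anterior basal edges at height `h1`/`h1_ant`; `setback_post`
#'   encodes the inclination angle beta = atan(setback_post / h1).
#' @param h1_ant Height of the anterior inflection marker, mm.
#' @param apex_y Position (y) of the dorsal apex marker; the apex height is
#'   `height`.
#' @param height Total scale height H = h1 + h2 (apex), mm.
#' @param tip_y,tip_z Hook tip marker, mm.
#' @param under_y,under_z Marker on the hook underside between tip and
#'   anterior inflection; controls how deeply the ventral cup is scooped.
#' @param xz_w_mid Half-width of the hook at station `xz_t_mid`, as a
#'   fraction of `width / 2`.
#' @param xz_t_mid Normalised spine station (0 base, 1 tip) of the mid-width
#'   marker.
#' @param xz_w_tip Half-width of the hook just behind the tip, as a fraction
#'   of `width / 2`.
#' @param species Optional species tag carried through to meshes and
#'   morphometric records.
#'
#' @return An object of class `scale_params`.
#' @examples
#' p <- scale_params()          # Rhyssoplax canariensis-like default
#' print(p)
#' @export
scale_params <- function(width = 0.48, length = 1, fillet_front = 0.03,
                         fillet_side = 0.04,
                         h1 = 0.2, setback_post = 0.0976,
                         setback_ant = 0.09, h1_ant = 0.18,
                         apex_y = 1.1, height = 0.59,
                         tip_y = 1.23, tip_z = 0.535,
                         under_y = 0.84, under_z = 0.345,
                         xz_w_mid = 0.79, xz_t_mid = 0.45, xz_w_tip = 0.62,
                         species = NULL) {
  p <- list(width = width, length = length,
            fillet_front = fillet_front, fillet_side = fillet_side,
            h1 = h1, setback_post = setback_post, setback_ant = setback_ant,
            h1_ant = h1_ant, apex_y = apex_y, height = height,
            tip_y = tip_y, tip_z = tip_z, under_y = under_y,
            under_z = under_z,
            xz_w_mid = xz_w_mid, xz_t_mid = xz_t_mid, xz_w_tip = xz_w_tip,
            species = species)
  class(p) <- "scale_params"
  validate_scale_params(p)
  p
}

#' Nominal imbrication and inclination angles implied by scale parameters
#'
#' beta is the tilt of the posterior basal edge away from the base-plane
#' normal (an upright prism has beta = 0). alpha is the interior angle at
#' the inflection point between the basal edge and the hook axis, where the
#' hook axis is the line fitted to the underside of the hook overhang (the
#' lower profile envelope forward of the base footprint — the surface that
#' covers the neighbouring scale; the same construction the mesh
#' morphometrics applies to the transverse silhouette). A straight prism
#' degenerates to alpha = 180.
#'
#' @param params A `scale_params` object.
#' @return Named numeric vector with `alpha` and `beta`, degrees.
#' @export
nominal_angles <- function(params) {
  beta <- atan2(params$setback_post, params$h1) * 180 / pi
  outline <- yz_outline(params, n = 400)
  y_front <- params$length / 2
  y_max <- max(outline[, 1])
  if (y_max <= y_front + 1e-9 * params$length) {
    alpha <- 180   # no overhang at all (vertical-extrusion degenerate)
  } else {
    yy <- seq(y_front + 0.01 * (y_max - y_front), y_max - 1e-6 * params$length,
              length.out = 80)
    zlo <- outline_lower_envelope(outline, yy)
    delta <- underside_elevation(yy, zlo)
    alpha <- if (is.na(delta)) 180 else 180 - beta - delta
  }
  c(alpha = alpha, beta = beta)
}

abort_validation <- function(msg, field = NULL) {
  stop(structure(class = c("chiton_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), field = field)))
}

abort_geometry <- function(msg) {
  stop(structure(class = c("chiton_geometry_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_parse <- function(msg) {
  stop(structure(class = c("chiton_parse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Validate scale parameters
#'
#' Checks positivity of lengths, the ordering 0 < h1 < H, fillet
#' feasibility, and the overlap capability condition alpha + beta < 180
#' degrees. Violations raise a condition of class
#' `chiton_validation_error` naming the offending parameter.
#'
#' @param p A `scale_params` object (or plain named list of the 17 values).
#' @return `p`, invisibly, if valid.
#' @export
validate_scale_params <- function(p) {
  num_fields <- setdiff(unlist(scale_param_names()), character(0))
  for (f in num_fields) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v))
      abort_validation(sprintf("parameter '%s' must be a finite number", f), f)
  }
  for (f in c("width", "length", "h1", "h1_ant", "height"))
    if (p[[f]] <= 0)
      abort_validation(sprintf("parameter '%s' must be > 0", f), f)
  for (f in c("fillet_front", "fillet_side"))
    if (p[[f]] < 0)
      abort_validation(sprintf("parameter '%s' must be >= 0", f), f)
  if (p$h1 >= p$height)
    abort_validation("'h1' must satisfy 0 < h1 < height", "h1")
  if (p$h1_ant >= p$height)
    abort_validation("'h1_ant' must satisfy 0 < h1_ant < height", "h1_ant")
  if (p$fillet_front > 0.45 * p$width || p$fillet_side > 0.45 * p$length)
    abort_validation("fillet radius too large for the base diamond",
                     "fillet_front")
  if (p$xz_w_mid <= 0 || p$xz_w_mid > 1.5)
    abort_validation("'xz_w_mid' must lie in (0, 1.5]", "xz_w_mid")
  if (p$xz_w_tip <= 0 || p$xz_w_tip > 1)
    abort_validation("'xz_w_tip' must lie in (0, 1]", "xz_w_tip")
  if (p$xz_t_mid <= 0 || p$xz_t_mid >= 1)
    abort_validation("'xz_t_mid' must lie in (0, 1)", "xz_t_mid")
  ang <- nominal_angles(p)
  if (ang["alpha"] <= 0)
    abort_validation("implied imbrication angle alpha outside (0, 180]",
                     "tip_y")
  if (ang["beta"] < 0 || ang["beta"] >= 90)
    abort_validation("implied inclination angle beta outside [0, 90)",
                     "setback_post")
  # alpha == 180 exactly is the degenerate straight-extrusion sentinel
  # (no hook at all), which is permitted; anything else at or beyond 180
  # cannot overlap its neighbour
  if (ang["alpha"] + ang["beta"] >= 180 && ang["alpha"] != 180)
    abort_validation(paste0("non-overlapping geometry: alpha + beta = ",
                            sprintf("%.1f", ang["alpha"] + ang["beta"]),
                            " >= 180 degrees (overlap capability violated)"),
                     "tip_z")
  invisible(p)
}

#' Uniformly scale all length parameters
#'
#' Multiplies every length-valued parameter by `s`; dimensionless fractions
#' (the XZ width fractions and station) are untouched, so the scale shape is
#' geometrically similar and all angles are preserved.
#'
#' @param params A `scale_params` object.
#' @param s Positive scale factor.
#' @return A new `scale_params` object.
#' @export
scale_params_scale <- function(params, s) {
  if (!is.numeric(s) || s <= 0) abort_validation("scale factor must be > 0")
  len_fields <- c("width", "length", "fillet_front", "fillet_side",
                  "h1", "setback_post", "setback_ant", "h1_ant",
                  "apex_y", "height", "tip_y", "tip_z", "under_y", "under_z")
  for (f in len_fields) params[[f]] <- params[[f]] * s
  params
}

#' @export
print.scale_params <- function(x, ...) {
  ang <- nominal_angles(x)
  cat("Girdle scale parameters (17 free parameters, 20 markers)\n")
  if (!is.null(x$species)) cat("  species:", x$species, "\n")
  cat(sprintf("  base:   W = %.4g mm, L = %.4g mm (fillets %.3g / %.3g)\n",
              x$width, x$length, x$fillet_front, x$fillet_side))
  cat(sprintf("  profile: H = %.4g mm, h1 = %.4g mm (h1/H = %.2f)\n",
              x$height, x$h1, x$h1 / x$height))
  cat(sprintf("  nominal angles: alpha = %.1f deg, beta = %.1f deg\n",
              ang["alpha"], ang["beta"]))
  invisible(x)
}
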
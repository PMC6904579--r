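# Small 2-D computational-geometry helpers: simple-polygon moments, the
# hook-underside line fit shared by the parametric generator and the mesh
# morphometrics (two independent routes to the same imbrication angle),
# outline envelopes and a point-in-polygon test.

# Signed area, centroid and central second moments of a simple polygon
# (k x 2, implicitly closed).
poly_moments <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-14)
    return(list(area = 0, centroid = c(NA, NA), mu = c(0, 0, 0)))
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  Ixx <- sum((x^2 + x * x2 + x2^2) * cr) / 12       # integral of x^2 dA
  Iyy <- sum((y^2 + y * y2 + y2^2) * cr) / 12
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  s <- sign(A)
  list(area = abs(A), centroid = c(cx, cy),
       mu = c(xx = s * Ixx - abs(A) * cx^2,
              yy = s * Iyy - abs(A) * cy^2,
              xy = s * Ixy - abs(A) * cx * cy))
}

# Hook-axis elevation (degrees) from the underside line of the hook
# overhang: the lower silhouette envelope z_lo sampled at forward
# positions yy (beyond the base footprint's front edge), fitted as a line
# over the rising flank that emerges from the notch.
underside_elevation <- function(yy, zlo, lead_frac = 0.12, top_frac = 0.5,
                                min_pts = 6) {
  ok <- is.finite(zlo)
  yy <- yy[ok]; zlo <- zlo[ok]
  if (length(zlo) < 3) return(NA_real_)
  # fit band: skip a fixed lead-in past the footprint edge (the anterior
  # basal face below the notch), then fit the lower part of the rise — the
  # flank emerging from the notch, where the angle is defined — excluding
  # the crest rounding
  y0 <- min(yy) + lead_frac * (max(yy) - min(yy))
  h_top <- min(zlo) + top_frac * (max(zlo) - min(zlo))
  i0 <- which(yy >= y0)[1]
  if (is.na(i0)) return(NA_real_)
  i1 <- i0
  while (i1 < length(yy) && zlo[i1 + 1] <= h_top) i1 <- i1 + 1
  sel <- i0:i1
  if (length(sel) < min_pts) sel <- i0:min(length(yy), i0 + min_pts - 1)
  if (length(sel) < 3) return(NA_real_)
  co <- stats::coef(stats::lm(zlo[sel] ~ yy[sel]))
  atan(unname(co[2])) * 180 / pi
}

# Lower envelope of a closed outline polygon: minimum z of the outline's
# crossings with the vertical line at each y.
outline_lower_envelope <- function(poly, yy) {
  vapply(yy, function(y) {
    g <- poly[, 1] - y
    n <- nrow(poly)
    i1 <- seq_len(n); i2 <- c(seq_len(n)[-1], 1)
    s1 <- g[i1]; s2 <- g[i2]
    cross <- which((s1 > 0 & s2 <= 0) | (s1 <= 0 & s2 > 0))
    if (!length(cross)) return(NA_real_)
    t <- s1[cross] / (s1[cross] - s2[cross])
    min(poly[cross, 2] + t * (poly[i2[cross], 2] - poly[cross, 2]))
  }, 0)
}

# Even-odd point-in-polygon test (polygon k x 2, implicitly closed).
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2])) {
      xint <- poly[j, 1] + (pt[2] - poly[j, 2]) /
        (poly[i, 2] - poly[j, 2]) * (poly[i, 1] - poly[j, 1])
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Closed YZ outline polygon of a parameter set: the profile curve runs
# from one base corner to the other, so it closes implicitly along the
# base-plane segment.
yz_outline <- function(params, n = 400) {
  yz_curve_points(params, n = n)
}
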
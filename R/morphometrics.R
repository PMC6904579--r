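# Mesh-based morphometrics: the scale descriptor set measured from
# projection contours along two orientations (transverse: along x onto the
# y-z plane; bottom: along -z onto the x-y plane), plus divergence-theorem
# volume and centroid.
#
# Conventions (shared with the generator):
#   beta  - tilt of the posterior basal silhouette edge away from the
#           base-plane normal (upright prism: beta = 0).
#   h1    - height of the posterior inflection point: where the posterior
#           silhouette edge departs from the fitted basal line
#           (two-threshold crossing with quadratic-bias removal).
#   alpha - interior angle at the inflection point between the basal edge
#           and the hook axis, the line fitted to the underside of the
#           hook overhang; a straight prism degenerates to alpha = 180.
#   A1    - transverse silhouette area forward of the vertical through the
#           anteriormost point of the base footprint (the hook overhang
#           that covers the neighbouring scale).

#' Projection contours of a scale mesh
#'
#' Computes the transverse silhouette (projection along x onto the y-z
#' plane) and the bottom silhouette (projection along -z onto the x-y
#' plane) by scanline union of triangle shadows, together with their areas.
#'
#' @param mesh A watertight `scale_mesh`.
#' @param n_scan Number of scanlines per projection.
#' @return List with `transverse` and `bottom`, each containing `polygon`
#'   (outer boundary, k x 2), `area` (mm^2), and the raw scanline data.
#' @export
project_contours <- function(mesh, n_scan = 600) {
  if (!mesh_is_watertight(mesh))
    abort_validation("mesh must be watertight for contour projection")
  if (nrow(mesh$faces) == 0) abort_validation("empty mesh")
  bb <- mesh_bbox(mesh)
  one <- function(scan_axis, out_axis) {
    lo <- bb[1, scan_axis]; hi <- bb[2, scan_axis]
    dz <- (hi - lo) / n_scan
    at <- lo + (seq_len(n_scan) - 0.5) * dz
    sc <- silhouette_scan(mesh, scan_axis, out_axis, at)
    area <- sum(sc$width) * dz
    ok <- which(sc$width > 0)
    omin <- vapply(sc$intervals[ok], function(iv) iv[1, 1], 0)
    omax <- vapply(sc$intervals[ok], function(iv) iv[nrow(iv), 2], 0)
    poly <- rbind(cbind(omax, sc$at[ok]),
                  cbind(rev(omin), rev(sc$at[ok])))
    # polygon is (out, scan); reorder columns to ascending axis order
    if (out_axis > scan_axis) poly <- poly[, c(2, 1)]
    list(polygon = poly, area = area, at = sc$at, intervals = sc$intervals,
         width = sc$width, lo = omin, hi = omax, ok = ok, d = dz)
  }
  list(transverse = one(3, 2), bottom = one(1, 2))
}

# Windowed mean curvature of a polyline resampled by arc length: the
# turning angle accumulated over a window of width `window_frac` of the
# total arc, divided by the window width. Insensitive to faceting because
# every facet kink inside the window contributes its full turn exactly
# once.
polyline_curvature <- function(pts, n_resample = 400, window_frac = 0.05) {
  rp <- resample_polyline(pts, n_resample)
  d <- diff(rp)
  phi <- atan2(d[, 2], d[, 1])
  phi <- cumsum(c(phi[1], atan2(sin(diff(phi)), cos(diff(phi)))))  # unwrap
  ds <- sqrt(rowSums(d^2))
  s_mid <- c(0, cumsum(ds)[-length(ds)]) + ds / 2  # arc position per segment
  stot <- sum(ds)
  w <- window_frac * stot
  sq <- seq(0, stot, length.out = n_resample)
  phi_lo <- stats::approx(s_mid, phi, xout = pmax(sq - w / 2, 0), rule = 2)$y
  phi_hi <- stats::approx(s_mid, phi, xout = pmin(sq + w / 2, stot), rule = 2)$y
  span <- pmin(sq + w / 2, stot) - pmax(sq - w / 2, 0)
  kw <- (phi_hi - phi_lo) / span
  list(points = rp, curvature = kw,
       s = c(0, cumsum(ds)), phi = phi)
}

#' Measure the morphometric descriptor set of a scale mesh
#'
#' Measures the full descriptor record from a watertight scale mesh in the
#' canonical frame: base extents W and L (from the base-plane footprint),
#' heights h1 / h2 / H, inclination angle beta, imbrication angle alpha,
#' transverse projection areas A1 / A2 / A_total, volume V and the volume
#' centroid, plus the derived ratios H/L, W/L, h1/H and A1/A_total.
#'
#' @param mesh A watertight `scale_mesh` in the canonical frame (use
#'   [canonical_pose()] first for externally supplied meshes).
#' @param n_scan Number of silhouette scanlines.
#' @return An object of class `morphometrics` (named list).
#' @examples
#' rec <- measure_scale(loft_scale(scale_params(), 32, 32))
#' rec$ratios
#' @export
measure_scale <- function(mesh, n_scan = 600) {
  if (!inherits(mesh, "scale_mesh")) abort_validation("not a scale_mesh")
  if (!mesh_is_watertight(mesh))
    abort_validation("mesh must be watertight for morphometrics")
  V <- mesh_volume(mesh)
  if (V <= 0) abort_validation("mesh must enclose positive volume")
  bb <- mesh_bbox(mesh)
  H <- bb[2, 3] - bb[1, 3]
  z0 <- bb[1, 3]

  # base footprint from a cross-section just above the base plane
  seg <- mesh_section_segments(mesh, axis = 3, value = z0 + 1e-3 * H)
  fp <- rbind(seg$p1, seg$p2)
  if (!nrow(fp)) abort_validation("no base footprint found at z = 0")
  W <- max(fp[, 1]) - min(fp[, 1])
  L <- max(fp[, 2]) - min(fp[, 2])
  y_front <- max(fp[, 2])
  fp_ctr <- colMeans(fp)
  fp_poly <- fp[order(atan2(fp[, 2] - fp_ctr[2], fp[, 1] - fp_ctr[1])), ,
                drop = FALSE]

  # transverse silhouette scan
  dz <- H / n_scan
  at <- z0 + (seq_len(n_scan) - 0.5) * dz
  sc <- silhouette_scan(mesh, 3, 2, at)
  ok <- which(sc$width > 0)
  ymin <- vapply(sc$intervals[ok], function(iv) iv[1, 1], 0)
  ymax <- vapply(sc$intervals[ok], function(iv) iv[nrow(iv), 2], 0)
  zz <- at[ok]
  A_total <- sum(sc$width) * dz
  clip_right <- function(iv, y0) {
    sum(pmax(0, iv[, 2] - pmax(iv[, 1], y0)))
  }
  A1 <- sum(vapply(sc$intervals[ok], clip_right, 0, y0 = y_front)) * dz
  A2 <- A_total - A1

  # posterior silhouette edge: inclination angle from the basal-line fit,
  # inflection height from the departure of the edge from that line
  post <- cbind(ymin, zz)
  fit <- (zz - z0) >= 0.02 * H & (zz - z0) <= 0.15 * H
  co <- stats::coef(stats::lm(ymin[fit] ~ zz[fit]))
  beta <- atan(unname(co[2])) * 180 / pi
  # signed perpendicular deviation of the edge from the basal line
  nrm <- c(1, -co[2]) / sqrt(1 + co[2]^2)
  dev <- (ymin - (co[1] + co[2] * zz)) * nrm[1]
  dev <- abs(dev)
  pc <- polyline_curvature(post)
  s_raw <- c(0, cumsum(sqrt(rowSums(diff(post)^2))))
  turn_total <- abs(pc$phi[length(pc$phi)] - pc$phi[1]) * 180 / pi
  delta <- 0.005 * H
  first_cross <- function(th) {
    i <- which(dev >= th)
    i <- i[i > max(which(fit))]        # beyond the fitted basal band
    if (!length(i)) return(NA_real_)
    i1 <- i[1]
    if (i1 == 1) return(s_raw[1])
    f <- (th - dev[i1 - 1]) / (dev[i1] - dev[i1 - 1])
    s_raw[i1 - 1] + f * (s_raw[i1] - s_raw[i1 - 1])
  }
  s1 <- first_cross(delta)
  s2 <- first_cross(4 * delta)
  multi_inflection <- FALSE
  if (turn_total < 5 || is.na(s2)) {
    degenerate <- TRUE
    h1 <- H
    alpha <- 180
  } else {
    degenerate <- FALSE
    s_star <- max(0, 2 * s1 - s2)   # remove the quadratic-departure bias
    h1 <- stats::approx(s_raw, zz - z0, xout = s_star)$y
    # double curvature: opposite-signed bending runs beyond the onset,
    # each accumulating a substantial turn (not just local faceting)
    ks <- pc$curvature
    sel <- which(pc$points[, 2] - z0 > h1 + 0.05 * H)
    if (length(sel) > 4) {
      dstep <- pc$s[length(pc$s)] / length(pc$s)
      kref <- max(abs(ks[sel]), 1e-12)
      sgn <- sign(ks[sel])
      sgn[abs(ks[sel]) < 0.2 * kref] <- 0
      r <- rle(sgn)
      ends <- cumsum(r$lengths)
      turns <- vapply(seq_along(r$lengths), function(i) {
        ii <- sel[(ends[i] - r$lengths[i] + 1):ends[i]]
        sum(ks[ii]) * dstep * 180 / pi
      }, 0)
      multi_inflection <- any(turns >= 12) && any(turns <= -12)
    }
  }

  # hook tip and imbrication angle (hook axis = the underside line of the
  # hook overhang, scanned along y beyond the base footprint's front edge)
  kt <- which.max(ymax)
  tip <- c(ymax[kt], zz[kt] - z0)
  if (!degenerate) {
    y_max <- max(ymax)
    if (y_max > y_front + 1e-9 * L) {
      aty <- seq(y_front + 0.01 * (y_max - y_front), y_max - 1e-6 * L,
                 length.out = 120)
      scy <- silhouette_scan(mesh, 2, 3, aty)
      zlo <- vapply(scy$intervals, function(iv)
        if (nrow(iv)) iv[1, 1] else NA_real_, 0)
      delta <- underside_elevation(aty, zlo - z0)
      alpha <- if (is.na(delta)) 180 else 180 - beta - delta
    } else {
      alpha <- 180
      degenerate <- TRUE
    }
  }

  ctr <- mesh_centroid(mesh)
  rec <- list(
    W = W, L = L, h1 = h1, h2 = H - h1, H = H,
    alpha = unname(alpha), beta = unname(beta),
    A1 = A1, A2 = A2, A_total = A_total,
    V = V, centroid = ctr,
    footprint = fp_poly,
    tip = tip,
    ratios = c(H_L = H / L, W_L = W / L, h1_H = h1 / H,
               A1_At = A1 / A_total),
    flags = c(degenerate = degenerate, multi_inflection = multi_inflection),
    species = if (inherits(mesh$provenance, "scale_params"))
      mesh$provenance$species else NULL)
  class(rec) <- "morphometrics"
  rec
}

#' @export
print.morphometrics <- function(x, ...) {
  cat("Scale morphometrics", if (!is.null(x$species)) paste0("(", x$species, ")"), "\n")
  cat(sprintf("  W = %.4g  L = %.4g  H = %.4g  h1 = %.4g  h2 = %.4g mm\n",
              x$W, x$L, x$H, x$h1, x$h2))
  cat(sprintf("  alpha = %.1f deg  beta = %.1f deg\n", x$alpha, x$beta))
  cat(sprintf("  A1 = %.4g  A2 = %.4g  A_total = %.4g mm^2  V = %.4g mm^3\n",
              x$A1, x$A2, x$A_total, x$V))
  cat(sprintf("  H/L = %.3f  W/L = %.3f  h1/H = %.3f  A1/At = %.3f\n",
              x$ratios["H_L"], x$ratios["W_L"], x$ratios["h1_H"],
              x$ratios["A1_At"]))
  cat(sprintf("  centroid = (%.3g, %.3g, %.3g) mm\n", x$centroid[1],
              x$centroid[2], x$centroid[3]))
  if (any(x$flags)) cat("  flags:", names(x$flags)[x$flags], "\n")
  invisible(x)
}

#' Basal centre-of-mass check
#'
#' Tests whether the volume centroid of a measured scale lies within the
#' basal region: the vertical line through the centre of mass must pass
#' through the supporting base footprint, so a normal compressive load
#' cannot tip the scale about a base edge. (A scale whose mass hangs out
#' over the hook overhang fails; the height of the centroid is immaterial
#' for tilting under vertical load.)
#'
#' @param record A `morphometrics` record.
#' @return Logical scalar.
#' @export
basal_com_check <- function(record) {
  if (!inherits(record, "morphometrics")) abort_validation("not a morphometrics record")
  fp <- record$footprint
  if (is.null(fp)) return(NA)
  point_in_polygon(record$centroid[1:2], fp)
}

#' Re-pose an externally supplied mesh into the canonical frame
#'
#' Translates the base onto the z = 0 plane, aligns the base footprint's
#' principal axes with x/y (long axis to y) by PCA, and orients +y toward
#' the hook (the side containing the upper-mesh centroid). Ties in the PCA
#' sign are broken by requiring the apex-containing side to map to +y.
#'
#' @param mesh A `scale_mesh`.
#' @return A re-posed `scale_mesh`.
#' @export
canonical_pose <- function(mesh) {
  v <- mesh$vertices
  zr <- range(v[, 3])
  # assume dorsal is already +z (supported meshes); lift base to z = 0
  v[, 3] <- v[, 3] - zr[1]
  hz <- zr[2] - zr[1]
  basal <- v[v[, 3] < 0.08 * hz, 1:2, drop = FALSE]
  ctr <- colMeans(basal)
  cv <- stats::cov(basal)
  ev <- eigen(cv)
  long <- ev$vectors[, 1]   # largest footprint variance -> length axis
  yax <- long / sqrt(sum(long^2))
  top <- v[v[, 3] > 0.5 * hz, 1:2, drop = FALSE]
  if (nrow(top) && sum((colMeans(top) - ctr) * yax) < 0) yax <- -yax
  xax <- c(yax[2], -yax[1])
  R2 <- rbind(xax, yax)
  vv <- cbind((v[, 1:2] - matrix(ctr, nrow(v), 2, byrow = TRUE)) %*% t(R2),
              v[, 3])
  colnames(vv) <- NULL
  out <- mesh
  out$vertices <- vv
  out
}

#' Plot the projection contours of a scale mesh
#'
#' @param x A `scale_mesh`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scale_mesh <- function(x, ...) {
  pc <- project_contours(x, n_scan = 300)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  tp <- pc$transverse$polygon
  graphics::plot(tp, type = "l", asp = 1, xlab = "y (mm)", ylab = "z (mm)",
                 main = "transverse", ...)
  bp <- pc$bottom$polygon
  graphics::plot(bp, type = "l", asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                 main = "bottom", ...)
  invisible(x)
}
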
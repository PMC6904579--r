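# Principal scaffolding curves: filleted BASE diamond, YZ profile spline
# through 7 markers, XZ crown arch, and the medial spine used for lofting.

# Natural cubic interpolating spline through 2-D points, chord-length
# parameterised, evaluated at n points. Returns a matrix with columns x, y.
spline2d <- function(pts, n = 400) {
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  if (any(d <= 0)) abort_geometry("coincident consecutive markers in curve")
  so <- seq(0, s[length(s)], length.out = n)
  cbind(stats::spline(s, pts[, 1], xout = so, method = "natural")$y,
        stats::spline(s, pts[, 2], xout = so, method = "natural")$y)
}

# Cubic interpolating spline with prescribed end slopes (clamped); a NULL
# slope makes that end natural (zero second derivative). x must be
# strictly increasing.
clamped_spline_eval <- function(x, y, xout, d0, dn) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  r <- numeric(n)
  if (is.null(d0)) {
    A[1, 1] <- 1
  } else {
    A[1, 1] <- 2 * h[1]; A[1, 2] <- h[1]
    r[1] <- 6 * ((y[2] - y[1]) / h[1] - d0)
  }
  if (n > 2) for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    r[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  if (is.null(dn)) {
    A[n, n] <- 1
  } else {
    A[n, n - 1] <- h[n - 1]; A[n, n] <- 2 * h[n - 1]
    r[n] <- 6 * (dn - (y[n] - y[n - 1]) / h[n - 1])
  }
  M <- solve(A, r)
  j <- pmin(pmax(findInterval(xout, x), 1), n - 1)
  hj <- h[j]
  t <- (xout - x[j]) / hj
  (1 - t) * y[j] + t * y[j + 1] +
    hj^2 / 6 * (((1 - t)^3 - (1 - t)) * M[j] + (t^3 - t) * M[j + 1])
}

# Clamped 2-D spline through points with prescribed unit end tangents,
# chord-length parameterised.
spline2d_clamped <- function(pts, tan0, tan1, n = 400) {
  d <- sqrt(rowSums(diff(pts)^2))
  if (any(d <= 0)) abort_geometry("coincident consecutive markers in curve")
  s <- c(0, cumsum(d))
  so <- seq(0, s[length(s)], length.out = n)
  cbind(clamped_spline_eval(s, pts[, 1], so, tan0[1], tan1[1]),
        clamped_spline_eval(s, pts[, 2], so, tan0[2], tan1[2]))
}

# clamped at the start, natural at the end
spline2d_clamped_nat <- function(pts, tan0, n = 400) {
  d <- sqrt(rowSums(diff(pts)^2))
  if (any(d <= 0)) abort_geometry("coincident consecutive markers in curve")
  s <- c(0, cumsum(d))
  so <- seq(0, s[length(s)], length.out = n)
  cbind(clamped_spline_eval(s, pts[, 1], so, tan0[1], NULL),
        clamped_spline_eval(s, pts[, 2], so, tan0[2], NULL))
}

# Closed filleted diamond in the z = 0 plane, sampled at n points ordered
# counter-clockwise starting near the +x side vertex. Circular-arc fillets
# of radius rf at the front/back (+/-y) vertices and rs at the side (+/-x)
# vertices.
# Pre-fillet half-extents of the base diamond: the diamond is enlarged so
# that the filleted contour still attains the nominal width/length extents
# (fillets cut the vertices back).
base_prefillet <- function(params) {
  W <- params$width / 2
  L <- params$length / 2
  Wv <- W; Lv <- L
  for (it in 1:4) {
    half_side <- atan2(Lv, Wv)   # half interior angle at the side vertices
    half_frnt <- atan2(Wv, Lv)
    cut_s <- params$fillet_side * (1 / sin(half_side) - 1)
    cut_f <- params$fillet_front * (1 / sin(half_frnt) - 1)
    Wv <- W + cut_s
    Lv <- L + cut_f
  }
  c(Wv = Wv, Lv = Lv)
}

base_contour <- function(params, n = 128) {
  pf <- base_prefillet(params)
  Wv <- pf["Wv"]; Lv <- pf["Lv"]
  verts <- rbind(c(Wv, 0), c(0, Lv), c(-Wv, 0), c(0, -Lv))
  radii <- c(params$fillet_side, params$fillet_front,
             params$fillet_side, params$fillet_front)
  segs <- list()
  tangent_pts <- matrix(0, 4, 4)  # entry/exit tangency points per corner
  for (k in 1:4) {
    v <- verts[k, ]
    prev <- verts[(k - 2) %% 4 + 1, ]
    nxt <- verts[k %% 4 + 1, ]
    e1 <- (prev - v) / sqrt(sum((prev - v)^2))  # toward previous vertex
    e2 <- (nxt - v) / sqrt(sum((nxt - v)^2))    # toward next vertex
    r <- radii[k]
    half <- acos(sum(e1 * e2)) / 2
    t_off <- if (r > 0) r / tan(half) else 0
    p1 <- v + e1 * t_off  # tangency on incoming edge
    p2 <- v + e2 * t_off  # tangency on outgoing edge
    tangent_pts[k, ] <- c(p1, p2)
    if (r > 0) {
      ctr <- v + (e1 + e2) / sqrt(sum((e1 + e2)^2)) * r / sin(half)
      a1 <- atan2(p1[2] - ctr[2], p1[1] - ctr[1])
      a2 <- atan2(p2[2] - ctr[2], p2[1] - ctr[1])
      da <- (a2 - a1) %% (2 * pi)
      if (da > pi) da <- da - 2 * pi  # shorter arc
      aa <- seq(a1, a1 + da, length.out = 16)
      segs[[k]] <- cbind(ctr[1] + r * cos(aa), ctr[2] + r * sin(aa))
    } else {
      segs[[k]] <- rbind(v)
    }
  }
  # walk corners 1..4 (CCW: +x, +y, -x, -y) joining arcs with straight edges
  pts <- do.call(rbind, segs)
  # resample to n points uniformly by arc length, closed
  closed <- rbind(pts, pts[1, , drop = FALSE])
  d <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(d))
  keep <- c(TRUE, d > 1e-12)
  closed <- closed[keep, , drop = FALSE]
  s <- s[keep]
  so <- seq(0, s[length(s)], length.out = n + 1)[-(n + 1)]
  cbind(stats::approx(s, closed[, 1], xout = so)$y,
        stats::approx(s, closed[, 2], xout = so)$y)
}

# The 7 YZ profile markers (y, z), ordered along the open curve:
# posterior base -> posterior inflection -> apex -> hook tip -> underside
# -> anterior inflection -> anterior base.
yz_markers <- function(params) {
  p <- params
  rbind(m1 = c(-p$length / 2, 0),
        m2 = c(-p$length / 2 + p$setback_post, p$h1),
        m3 = c(p$apex_y, p$height),
        m4 = c(p$tip_y, p$tip_z),
        m5 = c(p$under_y, p$under_z),
        m6 = c(p$length / 2 + p$setback_ant, p$h1_ant),
        m7 = c(p$length / 2, 0))
}

# The 5 XZ crown-arch markers (x, z): base corners (inherited W from BASE),
# mid-width pair, apex (inherits H from YZ).
xz_markers <- function(params) {
  W2 <- params$width / 2
  zm <- params$h1 + params$xz_t_mid * (params$height - params$h1)
  rbind(c(-W2, 0),
        c(-W2 * params$xz_w_mid, zm),
        c(0, params$height),
        c(W2 * params$xz_w_mid, zm),
        c(W2, 0))
}

# The YZ profile polyline (no validation; used by both the curve builder
# and the nominal-angle computation). The basal profile edges are straight
# (the base is prismatic: its cross-section does not change along its
# height); the hook curve is a clamped cubic spline meeting them
# tangentially at the inflection markers, so the whole curve is C1. The
# hook is split at the apex marker with horizontal clamped tangents so the
# apex is the true height maximum (H is exact, no spline overshoot).
yz_curve_points <- function(params, n = 400) {
  ym <- yz_markers(params)
  seg_n <- max(20, n %/% 8)
  lin <- function(a, b, k) cbind(seq(a[1], b[1], length.out = k),
                                 seq(a[2], b[2], length.out = k))
  t_post <- (ym[2, ] - ym[1, ]) / sqrt(sum((ym[2, ] - ym[1, ])^2))
  t_ant <- (ym[7, ] - ym[6, ]) / sqrt(sum((ym[7, ] - ym[6, ])^2))
  # the basal tangents are carried into the hook at reduced weight so the
  # dorsal curve turns forward soon after the inflection (full-weight
  # clamps keep the curve climbing along the basal direction for most of
  # the chord, which over-inflates the dorsal dome)
  # the anterior inflection (m6) is the notch corner where the hook springs
  # from the base and where the imbrication angle is defined: the underside
  # meets the basal edge in a corner (natural end), not tangentially
  kt <- 0.5
  hookA <- spline2d_clamped(ym[2:3, ], kt * t_post, c(1, 0),
                            n = max(60, n %/% 3))
  hookB <- spline2d_clamped_nat(ym[3:6, ], c(1, 0), n = n)
  rbind(lin(ym[1, ], ym[2, ], seg_n)[-seg_n, , drop = FALSE],
        hookA[-nrow(hookA), , drop = FALSE],
        hookB,
        lin(ym[6, ], ym[7, ], seg_n)[-1, , drop = FALSE])
}

#' Build the principal scaffolding curves of a scale
#'
#' Constructs the three principal curves of the parametric scale model (the
#' filleted BASE diamond in the z = 0 plane, the YZ profile spline through
#' its 7 markers in the x = 0 plane, and the XZ crown arch) together with
#' the 20 labelled markers they interpolate. All curves are natural cubic
#' splines with chord-length parameterisation.
#'
#' @param params A `scale_params` object.
#' @param n Number of samples per curve.
#' @return An object of class `principal_curves`: list with `base_contour`
#'   (closed, n x 2, x-y), `yz_curve` (n x 2, y-z), `xz_curve` (n x 2, x-z),
#'   `markers` (20 x 3 matrix of labelled 3-D markers) and `params`.
#' @export
build_principal_curves <- function(params, n = 400) {
  validate_scale_params(params)
  bc <- base_contour(params, n = max(64, n %/% 4))
  ym <- yz_markers(params)
  yz <- yz_curve_points(params, n = n)
  xm <- xz_markers(params)
  xz <- spline2d(xm, n = n)

  # 20 labelled 3-D markers: 8 BASE (4 vertices + 4 fillet-arc midpoints),
  # 7 YZ, 5 XZ.
  W2 <- params$width / 2; L2 <- params$length / 2
  diag_mid <- function(a, b) {  # fillet midpoint: closest contour point to corner midpoint
    target <- (a + b) / 2
    i <- which.min((bc[, 1] - target[1])^2 + (bc[, 2] - target[2])^2)
    bc[i, ]
  }
  bverts <- rbind(c(W2, 0), c(0, L2), c(-W2, 0), c(0, -L2))
  bmids <- rbind(diag_mid(bverts[1, ] * 2, bverts[2, ] * 0) , # near +x vertex
                 diag_mid(bverts[2, ] * 2, bverts[2, ] * 0),
                 diag_mid(bverts[3, ] * 2, bverts[3, ] * 0),
                 diag_mid(bverts[4, ] * 2, bverts[4, ] * 0))
  base_m <- cbind(rbind(bverts, bmids), 0)
  rownames(base_m) <- c("base_vx_px", "base_vx_py", "base_vx_mx", "base_vx_my",
                        "base_fl_px", "base_fl_py", "base_fl_mx", "base_fl_my")
  yz_m <- cbind(0, ym)
  rownames(yz_m) <- paste0("yz_", rownames(ym))
  xz_m <- cbind(xm[, 1], 0, xm[, 2])
  rownames(xz_m) <- paste0("xz_m", 1:5)
  markers <- rbind(base_m, yz_m, xz_m)
  colnames(markers) <- c("x", "y", "z")

  out <- list(base_contour = bc, yz_curve = yz, xz_curve = xz,
              markers = markers, params = params)
  class(out) <- "principal_curves"
  out
}

# Split the sampled YZ curve into its posterior (base -> tip) and anterior
# (base -> tip) branches at the hook-tip marker.
yz_branches <- function(curves) {
  yz <- curves$yz_curve
  tip <- yz_markers(curves$params)[4, ]
  i <- which.min((yz[, 1] - tip[1])^2 + (yz[, 2] - tip[2])^2)
  list(back = yz[1:i, , drop = FALSE],
       front = yz[nrow(yz):i, , drop = FALSE])
}

# Resample a polyline (k x 2) at m points equally spaced in arc length.
resample_polyline <- function(pts, m) {
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  keep <- c(TRUE, d > 1e-14)
  pts <- pts[keep, , drop = FALSE]
  s <- s[keep]
  so <- seq(0, s[length(s)], length.out = m)
  cbind(stats::approx(s, pts[, 1], xout = so)$y,
        stats::approx(s, pts[, 2], xout = so)$y)
}

polyline_arclength <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

# Crude O(n^2) self-intersection test for a polyline given as k x 2 matrix.
polyline_self_intersects <- function(pts) {
  n <- nrow(pts) - 1
  if (n < 3) return(FALSE)
  p1 <- pts[1:n, , drop = FALSE]; p2 <- pts[2:(n + 1), , drop = FALSE]
  for (i in 1:(n - 2)) {
    j <- (i + 2):n
    a1 <- p1[i, ]; a2 <- p2[i, ]
    d1 <- a2 - a1
    b1 <- p1[j, , drop = FALSE]; b2 <- p2[j, , drop = FALSE]
    db <- b2 - b1
    denom <- d1[1] * db[, 2] - d1[2] * db[, 1]
    lens <- sqrt(sum(d1^2)) * sqrt(rowSums(db^2))
    rel <- cbind(b1[, 1] - a1[1], b1[, 2] - a1[2])
    t <- (rel[, 1] * db[, 2] - rel[, 2] * db[, 1]) / denom
    u <- (rel[, 1] * d1[2] - rel[, 2] * d1[1]) / -denom
    hit <- abs(denom) > 1e-9 * lens & is.finite(t) & is.finite(u) &
      t > 1e-9 & t < 1 - 1e-9 & u > 1e-9 & u < 1 - 1e-9
    if (i == 1) hit[j == n & (1 %in% 1)] <- hit[j == n] # closed-curve guard (no-op for open)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Extract the medial spine of the YZ profile
#'
#' The spine is the medial curve of the YZ section: the locus of midpoints
#' of the posterior and anterior profile branches matched by normalised arc
#' length. It starts at the base-plane midpoint of the profile and ends at
#' the hook tip, and is returned arc-length parameterised.
#'
#' @param curves A `principal_curves` object.
#' @param n Number of spine samples.
#' @return A list with `points` (n x 2, y-z), `tangents` (n x 2, unit),
#'   `arclength` (total) and `t` (normalised stations in [0, 1]).
#' @export
extract_spine <- function(curves, n = 400) {
  if (polyline_self_intersects(curves$yz_curve))
    abort_geometry("YZ profile curve is self-intersecting")
  br <- yz_branches(curves)
  B <- resample_polyline(br$back, n)
  F <- resample_polyline(br$front, n)
  mid <- (B + F) / 2
  mid <- resample_polyline(mid, n)
  d <- sqrt(rowSums(diff(mid)^2))
  s <- c(0, cumsum(d))
  tg <- rbind(mid[2, ] - mid[1, ],
              (mid[3:n, ] - mid[1:(n - 2), ]) / 2,
              mid[n, ] - mid[n - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = mid, tangents = tg, arclength = s[n], t = s / s[n])
}
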
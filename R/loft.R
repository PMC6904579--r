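# Lofting: sweep closed cross-section profiles along the medial spine and
# stitch them into a watertight solid. Each section is framed by the chord
# between paired points of the two YZ profile branches (fore/aft extent)
# and by the XZ width law (lateral extent), with the profile shape
# morphing from the filleted base diamond in the prismatic region to a
# smooth crown section in the hook.

# Periodic natural cubic spline through values at uniform parameters
# (period 1); returns interpolant values at fractions `xf`.
periodic_cubic <- function(vals, xf) {
  n <- length(vals)
  h <- 1 / n
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (j in 1:n) {
    jm <- (j - 2) %% n + 1
    jp <- j %% n + 1
    A[j, jm] <- A[j, jm] + 1
    A[j, j] <- A[j, j] + 4
    A[j, jp] <- A[j, jp] + 1
    rhs[j] <- 6 / h^2 * (vals[jp] - 2 * vals[j] + vals[jm])
  }
  M <- solve(A, rhs)
  xf <- xf %% 1
  j <- pmin(floor(xf * n), n - 1)  # 0-based segment
  t <- (xf - j * h) / h
  j1 <- j + 1
  j2 <- j %% n + 2 - 1; j2 <- (j + 1) %% n + 1
  y1 <- vals[j1]; y2 <- vals[j2]
  m1 <- M[j1]; m2 <- M[j2]
  (1 - t) * y1 + t * y2 +
    h^2 / 6 * (((1 - t)^3 - (1 - t)) * m1 + (t^3 - t) * m2)
}

# Unit profile shapes sampled at n equally spaced angles starting at +u.
# The diamond shape is the base contour normalised to unit half-extents;
# the oval is the closed periodic cubic spline through the four unit
# extreme points (mirror-symmetric by construction).
profile_shapes <- function(params, n_profile,
                           style = c("crescent", "slab")) {
  style <- match.arg(style)
  th <- 2 * pi * (seq_len(n_profile) - 1) / n_profile
  bc <- base_contour(params, n = 512)
  un <- cbind(bc[, 1] / (params$width / 2), bc[, 2] / (params$length / 2))
  ang <- atan2(un[, 2], un[, 1]) %% (2 * pi)
  rad <- sqrt(rowSums(un^2))
  o <- order(ang)
  ang <- ang[o]; rad <- rad[o]
  # wrap for interpolation
  ang_w <- c(ang[length(ang)] - 2 * pi, ang, ang[1] + 2 * pi)
  rad_w <- c(rad[length(rad)], rad, rad[1])
  r_d <- stats::approx(ang_w, rad_w, xout = th)$y
  diamond <- cbind(r_d * cos(th), r_d * sin(th))
  xf <- th / (2 * pi)
  oval <- cbind(periodic_cubic(c(1, 0, -1, 0), xf),
                periodic_cubic(c(0, 1, 0, -1), xf))
  if (style == "crescent") {
    # crescent crown cross-section: the hook is a transversely arched
    # shell, full thickness at the midline (which carries the
    # transverse-silhouette descriptors) but thinning and drooping toward
    # the lateral flanks, the way the natural cup-like crown wraps over
    # its neighbours
    taper <- 0.9; arch <- 0.35
    u <- sign(oval[, 1]) * abs(oval[, 1])^0.7
    v <- oval[, 2] * (1 - taper * abs(u)^1.2) - arch * u^2
    oval <- cbind(u, v)
  } else {
    # slab crown cross-section: near-rectangular, with flat lateral flanks
    # whose normals point sideways (the simplified printable crown: the
    # crowns of neighbouring scales face each other across narrow vertical
    # slots, which is what makes the armor's interlocking
    # orientation-dependent)
    oval[, 1] <- sign(oval[, 1]) * abs(oval[, 1])^0.5
  }
  list(diamond = diamond, oval = oval, theta = th)
}

# Intersections of the line p + u * dir with a 2-D polyline; returns the
# signed offsets u of all crossings.
line_polyline_hits <- function(p, dir, poly) {
  nrm <- c(-dir[2], dir[1])
  g <- (poly[, 1] - p[1]) * nrm[1] + (poly[, 2] - p[2]) * nrm[2]
  n <- nrow(poly)
  s1 <- g[-n]; s2 <- g[-1]
  cross <- which((s1 > 0 & s2 <= 0) | (s1 <= 0 & s2 > 0))
  if (!length(cross)) return(numeric(0))
  t <- s1[cross] / (s1[cross] - s2[cross])
  px <- poly[cross, 1] + t * (poly[cross + 1, 1] - poly[cross, 1])
  py <- poly[cross, 2] + t * (poly[cross + 1, 2] - poly[cross, 2])
  (px - p[1]) * dir[1] + (py - p[2]) * dir[2]
}

# Lateral half-width law w(t) along the normalised spine: constant W/2 over
# the prismatic base, then a natural cubic through the mid-hook and
# near-tip half-width markers.
width_law <- function(params, t0) {
  W2 <- params$width / 2
  knots_t <- c(t0, params$xz_t_mid, 1)
  knots_w <- c(W2, W2 * params$xz_w_mid, W2 * params$xz_w_tip)
  if (params$xz_t_mid <= t0 + 0.05) {  # degenerate ordering; fall back
    knots_t <- c(t0, (t0 + 1) / 2, 1)
    knots_w <- c(W2, W2 * params$xz_w_mid, W2 * params$xz_w_tip)
  }
  function(t) {
    w <- ifelse(t <= t0, W2,
                stats::spline(knots_t, knots_w, xout = pmax(t, t0),
                              method = "natural")$y)
    pmax(w, 1e-4 * W2)
  }
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Loft a scale solid from its principal curves
#'
#' Generates the watertight triangulated solid of one girdle scale.
#' `n_sections` section planes are spaced equally along the medial spine;
#' each is framed by the chord between arc-matched points of the two YZ
#' profile branches (equal-height pairing inside the prismatic base, so
#' basal sections are exact horizontal diamonds) and by the XZ width law.
#' The closed profiles (base diamond in the prismatic region,
#' periodic-spline crown sections in the hook, smoothly blended in
#' between) are lofted and capped at the base and hook tip.
#'
#' @param params A `scale_params` object.
#' @param n_sections Number of section planes (>= 4).
#' @param n_profile Number of points per profile (>= 8).
#' @return A watertight `scale_mesh` in the canonical frame (base centroid
#'   at the origin, hook toward +y, dorsal +z), provenance = `params`.
#' @examples
#' m <- loft_scale(scale_params(), n_sections = 24, n_profile = 24)
#' mesh_volume(m)
#' @export
loft_scale <- function(params, n_sections = 64, n_profile = 64) {
  if (n_sections < 4) abort_validation("n_sections must be >= 4")
  if (n_profile < 8) abort_validation("n_profile must be >= 8")
  validate_scale_params(params)
  curves <- build_principal_curves(params, n = max(400, 4 * n_sections))
  if (polyline_self_intersects(curves$yz_curve))
    abort_geometry("YZ profile curve is self-intersecting")
  br <- yz_branches(curves)
  style <- attr(params, "crown_section")
  if (is.null(style)) style <- "crescent"
  shapes <- profile_shapes(params, n_profile, style = style)

  # Dense pairing of the two YZ branches; the chord between a pair spans
  # the section, its midpoint traces the medial spine. In the prismatic
  # base the branches are paired at equal height (sections stay horizontal
  # diamonds, exactly prismatic); above the inflection the remaining arcs
  # are matched proportionally.
  m <- max(800, 8 * n_sections)
  Bd <- resample_polyline(br$back, m)
  Fd0 <- resample_polyline(br$front, 4 * m)
  sF <- c(0, cumsum(sqrt(rowSums(diff(Fd0)^2))))
  h_eff <- 0.98 * min(params$h1, params$h1_ant)
  jB <- which(Bd[, 2] >= h_eff)[1]
  if (is.na(jB)) jB <- m
  jF <- which(Fd0[, 2] >= h_eff)[1]
  if (is.na(jF)) jF <- 4 * m
  Fd <- matrix(0, m, 2)
  for (j in seq_len(m)) {
    if (j < jB) {
      # equal-height pairing within the base
      z <- Bd[j, 2]
      kk <- which(Fd0[1:jF, 2] >= z)[1]
      if (is.na(kk)) kk <- jF
      Fd[j, ] <- Fd0[kk, ]
    } else {
      # proportional arc pairing in the hook
      fr <- (j - jB) / max(m - jB, 1)
      s_t <- sF[jF] + fr * (sF[4 * m] - sF[jF])
      kk <- findInterval(s_t, sF)
      kk <- min(max(kk, 1), 4 * m)
      Fd[j, ] <- Fd0[kk, ]
    }
  }
  Md <- (Bd + Fd) / 2
  s <- c(0, cumsum(sqrt(rowSums(diff(Md)^2))))
  t_of <- s / s[m]

  # station where the profile leaves the prismatic base
  j0 <- which(Bd[, 2] >= params$h1 | Fd[, 2] >= params$h1_ant)[1]
  if (is.na(j0)) j0 <- floor(m / 3)
  t0 <- t_of[j0]
  t_blend <- min(1, t0 + 0.12 * (1 - t0))
  wfun <- width_law(params, t0)

  t_last <- 1 - 0.5 / (n_sections - 1)
  tt <- seq(0, t_last, length.out = n_sections)[-1]
  rings <- vector("list", n_sections)
  # ring 1: the base contour itself, in the z = 0 plane
  r_d0 <- shapes$diamond
  rings[[1]] <- cbind(params$width / 2 * r_d0[, 1],
                      params$length / 2 * r_d0[, 2], 0)
  obliq <- numeric(length(tt))
  for (i in seq_along(tt)) {
    t <- tt[i]
    j <- which.min(abs(t_of - t))
    P <- Md[j, ]
    Bp <- Bd[j, ]; Fp <- Fd[j, ]
    ch <- Fp - Bp
    chl <- sqrt(sum(ch^2))
    if (chl < 1e-12)
      abort_geometry(sprintf(
        "section plane %d degenerates (branches touch before the tip)", i + 1))
    n2 <- ch / chl  # in-plane (y,z) trace of the section plane, back -> front
    # obliquity of the section relative to the local spine tangent
    jm <- max(2, min(m - 1, j))
    tg <- Md[jm + 1, ] - Md[jm - 1, ]
    tg <- tg / sqrt(sum(tg^2))
    obliq[i] <- abs(90 - acos(pmin(1, abs(sum(tg * n2)))) * 180 / pi)
    ctr <- 0
    r_s <- chl / 2   # +v maps to the front-branch end of the chord
    w <- wfun(t)
    b <- smoothstep((t - t0) / max(t_blend - t0, 1e-9))
    shp <- (1 - b) * shapes$diamond + b * shapes$oval
    xi <- w * shp[, 1]
    eta <- ctr + r_s * shp[, 2]
    yy <- P[1] + eta * n2[1]
    zz <- P[2] + eta * n2[2]
    zz[zz < 0] <- 0
    rings[[i + 1]] <- cbind(xi, yy, zz)
  }
  tipP <- Md[m, ]
  tip3 <- c(0, tipP[1], tipP[2])
  ctr3 <- c(0, 0, 0)

  verts <- do.call(rbind, rings)
  verts <- rbind(verts, tip3, ctr3)
  ntip <- nrow(verts) - 1L
  nctr <- nrow(verts)
  idx <- function(i, k) (i - 1L) * n_profile + ((k - 1L) %% n_profile) + 1L
  faces <- vector("list", 2 * n_sections + 2)
  fi <- 1
  for (i in seq_len(n_sections - 1)) {
    k <- seq_len(n_profile)
    a <- idx(i, k); bq <- idx(i, k + 1)
    cq <- idx(i + 1, k + 1); d <- idx(i + 1, k)
    faces[[fi]] <- cbind(a, bq, cq); fi <- fi + 1
    faces[[fi]] <- cbind(a, cq, d); fi <- fi + 1
  }
  k <- seq_len(n_profile)
  faces[[fi]] <- cbind(idx(n_sections, k), idx(n_sections, k + 1), ntip)
  fi <- fi + 1
  faces[[fi]] <- cbind(idx(1, k + 1), idx(1, k), nctr)
  mesh <- scale_mesh(verts, do.call(rbind, faces[seq_len(fi)]),
                     provenance = params)
  if (mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  if (mesh_volume(mesh) <= 0)
    abort_geometry("lofted solid has non-positive volume")
  attr(mesh, "section_obliquity") <- obliq
  mesh
}
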
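# Triangle-mesh container and the computational-geometry kernel used
# throughout: exact volume/centroid via the divergence theorem, watertight
# checks, plane cross-sections, silhouette scanlines, rigid transforms and
# point-triangle proximity queries.

#' Construct a triangle mesh
#'
#' @param vertices Numeric n x 3 matrix, mm.
#' @param faces Integer m x 3 matrix of 1-based vertex indices; triangles
#'   are oriented counter-clockwise seen from outside.
#' @param provenance Either the generating `scale_params` or the string
#'   `"external"`.
#' @return An object of class `scale_mesh`.
#' @export
scale_mesh <- function(vertices, faces, provenance = "external") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    abort_validation("vertices and faces must have 3 columns")
  if (max(faces) > nrow(vertices) || min(faces) < 1)
    abort_validation("face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 provenance = provenance),
            class = "scale_mesh")
}

face_corners <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh A `scale_mesh`.
#' @return Volume in mm^3 (positive for outward-oriented closed meshes).
#' @export
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  a <- fc$a; b <- fc$b; c <- fc$c
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Volume centroid of a closed mesh
#' @param mesh A `scale_mesh`.
#' @return Length-3 numeric vector, mm.
#' @export
mesh_centroid <- function(mesh) {
  fc <- face_corners(mesh)
  a <- fc$a; b <- fc$b; c <- fc$c
  det6 <- (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
           a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
           a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1]))
  V <- sum(det6) / 6
  ctr <- colSums((a + b + c) * det6) / (24 * V)
  unname(ctr)
}

triangle_areas <- function(mesh) {
  fc <- face_corners(mesh)
  u <- fc$b - fc$a; w <- fc$c - fc$a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Check that a mesh is watertight and consistently oriented
#'
#' Every directed edge must occur exactly once and its reverse exactly once
#' (so each undirected edge is shared by exactly two faces of opposite
#' traversal).
#'
#' @param mesh A `scale_mesh`.
#' @return Logical scalar.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(e[, 1], e[, 2])
  rkey <- paste(e[, 2], e[, 1])
  !anyDuplicated(key) && all(key %in% rkey)
}

#' Apply a rigid (or affine) transform to a mesh
#' @param mesh A `scale_mesh`.
#' @param rotation 3 x 3 matrix (applied first).
#' @param translation Length-3 vector (applied second).
#' @return Transformed `scale_mesh`.
#' @export
mesh_transform <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- mesh$vertices %*% t(rotation) +
    matrix(translation, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}

mesh_bbox <- function(mesh) {
  rbind(lo = apply(mesh$vertices, 2, min), hi = apply(mesh$vertices, 2, max))
}

#' @export
print.scale_mesh <- function(x, ...) {
  cat(sprintf("scale_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- mesh_bbox(x)
  cat(sprintf("  bbox x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  cat(sprintf("  watertight: %s, volume %.4g mm^3\n",
              mesh_is_watertight(x), mesh_volume(x)))
  invisible(x)
}

# Oriented cross-section segments of a mesh with the plane axis = value
# (axis 1 = x, 2 = y, 3 = z). Returns a list of matrices p1, p2 (k x 2)
# with in-plane coordinates of the two remaining axes (in ascending axis
# order), oriented so that the section polygon of the solid is traversed
# counter-clockwise in those coordinates when the plane normal is +axis.
mesh_section_segments <- function(mesh, axis = 3, value = 0) {
  v <- mesh$vertices; f <- mesh$faces
  w <- v[, axis]
  keep <- setdiff(1:3, axis)
  h <- cbind(w[f[, 1]], w[f[, 2]], w[f[, 3]]) - value
  side <- h > 0
  ns <- rowSums(side)
  cross <- which(ns == 1 | ns == 2)
  if (!length(cross)) return(list(p1 = matrix(0, 0, 2), p2 = matrix(0, 0, 2)))
  p1 <- matrix(0, length(cross), 2)
  p2 <- matrix(0, length(cross), 2)
  for (ii in seq_along(cross)) {
    i <- cross[ii]
    idx <- f[i, ]
    hh <- h[i, ]
    pos <- which(hh > 0); neg <- which(hh <= 0)
    # the lone vertex (on one side) and the opposite edge
    lone <- if (length(pos) == 1) pos else neg
    oth <- setdiff(1:3, lone)
    A <- v[idx[lone], ]
    B <- v[idx[oth[1]], ]; C <- v[idx[oth[2]], ]
    tB <- hh[lone] / (hh[lone] - hh[oth[1]])
    tC <- hh[lone] / (hh[lone] - hh[oth[2]])
    PB <- A + tB * (B - A)
    PC <- A + tC * (C - A)
    # orient the segment along plane_normal x face_normal so the solid's
    # cross-section boundary runs counter-clockwise about the +axis normal
    va <- v[idx[1], ]; vb <- v[idx[2], ]; vc <- v[idx[3], ]
    nt <- c((vb[2] - va[2]) * (vc[3] - va[3]) - (vb[3] - va[3]) * (vc[2] - va[2]),
            (vb[3] - va[3]) * (vc[1] - va[1]) - (vb[1] - va[1]) * (vc[3] - va[3]),
            (vb[1] - va[1]) * (vc[2] - va[2]) - (vb[2] - va[2]) * (vc[1] - va[1]))
    ez <- c(0, 0, 0); ez[axis] <- 1
    dvec <- c(ez[2] * nt[3] - ez[3] * nt[2],
              ez[3] * nt[1] - ez[1] * nt[3],
              ez[1] * nt[2] - ez[2] * nt[1])
    if (sum((PC - PB) * dvec) >= 0) { s1 <- PB; s2 <- PC } else { s1 <- PC; s2 <- PB }
    p1[ii, ] <- s1[keep]; p2[ii, ] <- s2[keep]
  }
  list(p1 = p1, p2 = p2)
}

# Signed area of the cross-section at axis = value via Green's theorem over
# the oriented boundary segments.
mesh_section_area <- function(mesh, axis = 3, value = 0) {
  seg <- mesh_section_segments(mesh, axis, value)
  if (!nrow(seg$p1)) return(0)
  a <- sum((seg$p1[, 1] + seg$p2[, 1]) * (seg$p2[, 2] - seg$p1[, 2])) / 2
  abs(a)
}

# Fast vectorised per-plane y-interval coverage of the mesh silhouette.
# For projection along `proj_axis`, scanning along `scan_axis` with
# coordinate values `at`, returns for each scan value the union of
# intervals of the third coordinate covered by the mesh's shadow, plus the
# summed width. Shadow of the solid = shadow of its boundary, so the
# y-extents of triangle/plane intersection segments suffice.
silhouette_scan <- function(mesh, scan_axis, out_axis, at) {
  v <- mesh$vertices; f <- mesh$faces
  w1 <- v[f[, 1], scan_axis]; w2 <- v[f[, 2], scan_axis]; w3 <- v[f[, 3], scan_axis]
  u1 <- v[f[, 1], out_axis];  u2 <- v[f[, 2], out_axis];  u3 <- v[f[, 3], out_axis]
  lo <- pmin(w1, w2, w3); hi <- pmax(w1, w2, w3)
  res <- vector("list", length(at))
  widths <- numeric(length(at))
  for (k in seq_along(at)) {
    z <- at[k]
    sel <- which(lo <= z & hi >= z)
    if (!length(sel)) { res[[k]] <- matrix(0, 0, 2); next }
    # intersection of each selected triangle with the plane: interval of u
    h1 <- w1[sel] - z; h2 <- w2[sel] - z; h3 <- w3[sel] - z
    umin <- rep(Inf, length(sel)); umax <- rep(-Inf, length(sel))
    edge_upd <- function(ha, hb, ua, ub, umin, umax) {
      crossing <- (ha > 0) != (hb > 0)
      crossing[!is.finite(ha) | !is.finite(hb)] <- FALSE
      t <- ha / (ha - hb)
      uu <- ua + t * (ub - ua)
      umin[crossing] <- pmin(umin[crossing], uu[crossing])
      umax[crossing] <- pmax(umax[crossing], uu[crossing])
      # vertices exactly on the plane
      on <- ha == 0
      umin[on] <- pmin(umin[on], ua[on])
      umax[on] <- pmax(umax[on], ua[on])
      list(umin, umax)
    }
    r <- edge_upd(h1, h2, u1[sel], u2[sel], umin, umax)
    r <- edge_upd(h2, h3, u2[sel], u3[sel], r[[1]], r[[2]])
    r <- edge_upd(h3, h1, u3[sel], u1[sel], r[[1]], r[[2]])
    umin <- r[[1]]; umax <- r[[2]]
    ok <- is.finite(umin) & is.finite(umax) & umax >= umin
    if (!any(ok)) { res[[k]] <- matrix(0, 0, 2); next }
    iv <- merge_intervals(cbind(umin[ok], umax[ok]))
    res[[k]] <- iv
    widths[k] <- sum(iv[, 2] - iv[, 1])
  }
  list(at = at, intervals = res, width = widths)
}

# Union of closed intervals given as k x 2 matrix; returns merged matrix
# sorted by lower end.
merge_intervals <- function(iv) {
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  lo <- iv[, 1]; hi <- iv[, 2]
  out_lo <- lo[1]; out_hi <- hi[1]
  res <- list()
  for (i in seq_len(nrow(iv))[-1]) {
    if (lo[i] <= out_hi + 1e-12) {
      out_hi <- max(out_hi, hi[i])
    } else {
      res[[length(res) + 1]] <- c(out_lo, out_hi)
      out_lo <- lo[i]; out_hi <- hi[i]
    }
  }
  res[[length(res) + 1]] <- c(out_lo, out_hi)
  do.call(rbind, res)
}

# ---- point-triangle proximity ------------------------------------------

# Squared distances from a set of points (n x 3) to a set of triangles
# (given by corner matrices a, b, c each m x 3): returns the minimum over
# all point-triangle pairs, with the realising pair. Chunked to bound
# memory.
points_tris_min_dist <- function(pts, a, b, c, chunk = 200L) {
  n <- nrow(pts); m <- nrow(a)
  best <- Inf; bp <- NULL; bq <- NULL
  for (s in seq(1, m, by = chunk)) {
    e <- min(m, s + chunk - 1)
    d <- point_tri_dist_block(pts, a[s:e, , drop = FALSE],
                              b[s:e, , drop = FALSE], c[s:e, , drop = FALSE])
    if (d$min < best) { best <- d$min; bp <- d$p; bq <- d$q }
  }
  list(min = best, p = bp, q = bq)
}

# Exact distance from n points to m triangles (dense n x m work arrays):
# the minimum of the in-face orthogonal projection (where its barycentric
# coordinates are valid) and the three point-segment distances. Returns the
# global minimum with witness points.
point_tri_dist_block <- function(pts, A, B, C) {
  n <- nrow(pts)
  # point-segment squared distance, n x m, plus foot parameters
  seg_d2 <- function(P, Qa, Qb) {
    E <- Qb - Qa
    ee <- rowSums(E * E)
    ee[ee < 1e-30] <- 1e-30
    tnum <- P %*% t(E) - matrix(rowSums(Qa * E), n, nrow(Qa), byrow = TRUE)
    tt <- sweep(tnum, 2, ee, `/`)
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    d2 <- 0
    Fx <- sweep(tt, 2, E[, 1], `*`); Fx <- sweep(Fx, 2, Qa[, 1], `+`)
    Fy <- sweep(tt, 2, E[, 2], `*`); Fy <- sweep(Fy, 2, Qa[, 2], `+`)
    Fz <- sweep(tt, 2, E[, 3], `*`); Fz <- sweep(Fz, 2, Qa[, 3], `+`)
    d2 <- (Fx - pts[, 1])^2 + (Fy - pts[, 2])^2 + (Fz - pts[, 3])^2
    list(d2 = d2, Fx = Fx, Fy = Fy, Fz = Fz)
  }
  E0 <- B - A; E1 <- C - A
  a11 <- rowSums(E0 * E0); a22 <- rowSums(E1 * E1); a12 <- rowSums(E0 * E1)
  b1 <- pts %*% t(E0) - matrix(rowSums(A * E0), n, nrow(A), byrow = TRUE)
  b2 <- pts %*% t(E1) - matrix(rowSums(A * E1), n, nrow(A), byrow = TRUE)
  det <- a11 * a22 - a12^2
  det[det < 1e-30] <- 1e-30
  s <- sweep(sweep(b1, 2, a22, `*`) - sweep(b2, 2, a12, `*`), 2, det, `/`)
  t <- sweep(sweep(b2, 2, a11, `*`) - sweep(b1, 2, a12, `*`), 2, det, `/`)
  inside <- s >= 0 & t >= 0 & s + t <= 1
  Qx <- sweep(s, 2, E0[, 1], `*`) + sweep(t, 2, E1[, 1], `*`)
  Qx <- sweep(Qx, 2, A[, 1], `+`)
  Qy <- sweep(s, 2, E0[, 2], `*`) + sweep(t, 2, E1[, 2], `*`)
  Qy <- sweep(Qy, 2, A[, 2], `+`)
  Qz <- sweep(s, 2, E0[, 3], `*`) + sweep(t, 2, E1[, 3], `*`)
  Qz <- sweep(Qz, 2, A[, 3], `+`)
  d2 <- (Qx - pts[, 1])^2 + (Qy - pts[, 2])^2 + (Qz - pts[, 3])^2
  d2[!inside] <- Inf
  for (edge in list(list(A, B), list(B, C), list(C, A))) {
    r <- seg_d2(pts, edge[[1]], edge[[2]])
    upd <- r$d2 < d2
    d2[upd] <- r$d2[upd]
    Qx[upd] <- r$Fx[upd]; Qy[upd] <- r$Fy[upd]; Qz[upd] <- r$Fz[upd]
  }
  i <- which.min(d2)
  ri <- (i - 1) %% n + 1
  list(min = sqrt(d2[i]),
       p = pts[ri, ],
       q = c(Qx[i], Qy[i], Qz[i]))
}

#' Minimum distance between two meshes
#'
#' Conservative two-sided vertex-to-surface distance with bounding-box
#' pruning: the minimum over vertices of one mesh against triangles of the
#' other, both ways. Exact whenever the closest approach involves a vertex;
#' for smoothly triangulated surfaces the error is bounded by the sagitta
#' of a facet.
#'
#' @param m1,m2 `scale_mesh` objects.
#' @param cutoff Only search within this distance (mm); returns `Inf` if the
#'   meshes are farther apart.
#' @return List with `distance`, and witness points `p1`, `p2` (or `Inf`
#'   distance and NULL witnesses).
#' @export
mesh_min_distance <- function(m1, m2, cutoff = Inf) {
  bb1 <- mesh_bbox(m1); bb2 <- mesh_bbox(m2)
  gap <- pmax(0, pmax(bb1[1, ] - bb2[2, ], bb2[1, ] - bb1[2, ]))
  if (sqrt(sum(gap^2)) > cutoff)
    return(list(distance = Inf, p1 = NULL, p2 = NULL))
  lo <- pmax(bb1[1, ], bb2[1, ]) - if (is.finite(cutoff)) cutoff else 0
  hi <- pmin(bb1[2, ], bb2[2, ]) + if (is.finite(cutoff)) cutoff else 0
  one_way <- function(ma, mb) {
    vin <- ma$vertices
    if (is.finite(cutoff)) {
      keep <- vin[, 1] >= lo[1] & vin[, 1] <= hi[1] &
        vin[, 2] >= lo[2] & vin[, 2] <= hi[2] &
        vin[, 3] >= lo[3] & vin[, 3] <= hi[3]
      vin <- vin[keep, , drop = FALSE]
    }
    if (!nrow(vin)) return(NULL)
    fc <- face_corners(mb)
    tlo <- pmin(fc$a, pmin(fc$b, fc$c)); thi <- pmax(fc$a, pmax(fc$b, fc$c))
    if (is.finite(cutoff)) {
      tk <- tlo[, 1] <= hi[1] & thi[, 1] >= lo[1] &
        tlo[, 2] <= hi[2] & thi[, 2] >= lo[2] &
        tlo[, 3] <= hi[3] & thi[, 3] >= lo[3]
      if (!any(tk)) return(NULL)
      fc <- list(a = fc$a[tk, , drop = FALSE], b = fc$b[tk, , drop = FALSE],
                 c = fc$c[tk, , drop = FALSE])
    }
    points_tris_min_dist(vin, fc$a, fc$b, fc$c)
  }
  r1 <- one_way(m1, m2)
  r2 <- one_way(m2, m1)
  cand <- list()
  if (!is.null(r1)) cand[[length(cand) + 1]] <- list(d = r1$min, p1 = r1$p, p2 = r1$q)
  if (!is.null(r2)) cand[[length(cand) + 1]] <- list(d = r2$min, p1 = r2$q, p2 = r2$p)
  if (!length(cand)) return(list(distance = Inf, p1 = NULL, p2 = NULL))
  best <- cand[[which.min(vapply(cand, function(x) x$d, 0))]]
  list(distance = best$d, p1 = best$p1, p2 = best$p2)
}

# Merge several meshes into one (no welding; used for export).
mesh_merge <- function(meshes) {
  nv <- 0L
  vs <- list(); fs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1]] <- m$vertices
    fs[[length(fs) + 1]] <- m$faces + nv
    nv <- nv + nrow(m$vertices)
  }
  scale_mesh(do.call(rbind, vs), do.call(rbind, fs), provenance = "merged")
}
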
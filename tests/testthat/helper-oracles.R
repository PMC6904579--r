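# Independent brute-force oracles used to cross-check the geometry kernel:
# a voxel/ray-parity volume and centroid oracle, a raster silhouette-area
# oracle, a point-in-projection test, and a brute-force polygon distance.
# All are deliberately simple and share no code with the implementation
# paths they check.

# volume and centroid by ray-parity column integration on an (nx x ny)
# grid of vertical columns
voxel_volume_centroid <- function(mesh, nx = 90, ny = 140) {
  bb <- rbind(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
  f <- mesh$faces; v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  dx <- (bb[2, 1] - bb[1, 1]) / nx
  dy <- (bb[2, 2] - bb[1, 2]) / ny
  xs <- bb[1, 1] + (seq_len(nx) - 0.5) * dx
  ys <- bb[1, 2] + (seq_len(ny) - 0.5) * dy
  vol <- 0; m1 <- c(0, 0, 0)
  for (x in xs) for (y in ys) {
    d1 <- (b[, 1] - a[, 1]) * (y - a[, 2]) - (b[, 2] - a[, 2]) * (x - a[, 1])
    d2 <- (c[, 1] - b[, 1]) * (y - b[, 2]) - (c[, 2] - b[, 2]) * (x - b[, 1])
    d3 <- (a[, 1] - c[, 1]) * (y - c[, 2]) - (a[, 2] - c[, 2]) * (x - c[, 1])
    ins <- which((d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0))
    if (length(ins) < 2) next
    zs <- vapply(ins, function(k) {
      A2 <- cbind(b[k, 1:2] - a[k, 1:2], c[k, 1:2] - a[k, 1:2])
      uv <- tryCatch(solve(A2, c(x, y) - a[k, 1:2]),
                     error = function(e) c(NA_real_, NA_real_))
      a[k, 3] + uv[1] * (b[k, 3] - a[k, 3]) + uv[2] * (c[k, 3] - a[k, 3])
    }, 0)
    zs <- sort(zs[is.finite(zs)])
    if (length(zs) %% 2 != 0) next
    lo <- zs[seq(1, length(zs), 2)]; hi <- zs[seq(2, length(zs), 2)]
    h <- sum(hi - lo)
    vol <- vol + h
    m1 <- m1 + c(x * h, y * h, sum((hi^2 - lo^2) / 2))
  }
  list(volume = vol * dx * dy, centroid = m1 / max(vol, 1e-300))
}

# raster silhouette area: fraction of pixel centres whose projection line
# meets any projected triangle
raster_silhouette_area <- function(mesh, proj = c("transverse", "bottom"),
                                   n = 250) {
  proj <- match.arg(proj)
  keep <- if (proj == "transverse") c(2, 3) else c(1, 2)
  f <- mesh$faces; v <- mesh$vertices
  a <- v[f[, 1], keep, drop = FALSE]
  b <- v[f[, 2], keep, drop = FALSE]
  c <- v[f[, 3], keep, drop = FALSE]
  lo <- pmin(apply(a, 2, min), apply(b, 2, min), apply(c, 2, min))
  hi <- pmax(apply(a, 2, max), apply(b, 2, max), apply(c, 2, max))
  du <- (hi[1] - lo[1]) / n; dv <- (hi[2] - lo[2]) / n
  us <- lo[1] + (seq_len(n) - 0.5) * du
  vs <- lo[2] + (seq_len(n) - 0.5) * dv
  hit <- 0L
  for (u in us) {
    sel <- which(pmin(a[, 1], b[, 1], c[, 1]) <= u &
                   pmax(a[, 1], b[, 1], c[, 1]) >= u)
    if (!length(sel)) next
    aa <- a[sel, , drop = FALSE]; bb <- b[sel, , drop = FALSE]
    cc <- c[sel, , drop = FALSE]
    for (w in vs) {
      d1 <- (bb[, 1] - aa[, 1]) * (w - aa[, 2]) - (bb[, 2] - aa[, 2]) * (u - aa[, 1])
      d2 <- (cc[, 1] - bb[, 1]) * (w - bb[, 2]) - (cc[, 2] - bb[, 2]) * (u - bb[, 1])
      d3 <- (aa[, 1] - cc[, 1]) * (w - cc[, 2]) - (aa[, 2] - cc[, 2]) * (u - cc[, 1])
      if (any((d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)))
        hit <- hit + 1L
    }
  }
  hit * du * dv
}

# brute-force minimum distance between two 2-D polygons (vertex-to-edge,
# both directions)
polygon_min_distance <- function(P1, P2) {
  seg_pt <- function(P, Q) {
    n <- nrow(Q); best <- Inf
    for (i in seq_len(n)) {
      a <- Q[i, ]; b <- Q[i %% n + 1, ]
      ab <- b - a
      t <- pmax(0, pmin(1, ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2]) /
                          sum(ab^2)))
      d2 <- (a[1] + t * ab[1] - P[, 1])^2 + (a[2] + t * ab[2] - P[, 2])^2
      best <- min(best, min(d2))
    }
    sqrt(best)
  }
  min(seg_pt(P1, P2), seg_pt(P2, P1))
}

# Sutherland-Hodgman convex clip, used as an independent oracle for fan
# cell areas (clip the plane rectangle by the four half-planes of a cell)
clip_convex <- function(poly, a, b) {
  n <- nrow(poly)
  out <- NULL
  d <- poly %*% a - b
  for (i in seq_len(n)) {
    j <- i %% n + 1
    if (d[i] >= 0) out <- rbind(out, poly[i, ])
    if ((d[i] >= 0) != (d[j] >= 0)) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# dorsal coverage fraction of the interior lattice cells of a uniform
# assembly (fraction of cell sample points lying under some scale's
# vertical projection)
coverage_fraction <- function(asm, n_grid = 70) {
  ids <- interior_ids(asm)
  pit <- asm$pitch
  tris <- lapply(seq_along(asm$placements), function(k) {
    m <- placed_scale_mesh(asm, k)
    f <- m$faces; v <- m$vertices
    list(a = v[f[, 1], , drop = FALSE], b = v[f[, 2], , drop = FALSE],
         c = v[f[, 3], , drop = FALSE],
         xr = range(v[, 1]), yr = range(v[, 2]))
  })
  covered <- 0L; total <- 0L
  for (id in ids) {
    ctr <- asm$placements[[id]]$translation[1:2]
    xs <- ctr[1] + (seq_len(n_grid) / n_grid - 0.5) * pit["sx"]
    for (xi in xs) {
      ys <- ctr[2] + (seq_len(n_grid) / n_grid - 0.5) * pit["sy"]
      ys <- ys[abs(xi - ctr[1]) / (pit["sx"] / 2) +
                 abs(ys - ctr[2]) / (pit["sy"] / 2) <= 1]
      if (!length(ys)) next
      total <- total + length(ys)
      cov <- rep(FALSE, length(ys))
      for (tr in tris) {
        if (xi < tr$xr[1] || xi > tr$xr[2]) next
        sel <- which(!cov & ys >= tr$yr[1] & ys <= tr$yr[2])
        for (j in sel) {
          y <- ys[j]
          d1 <- (tr$b[, 1] - tr$a[, 1]) * (y - tr$a[, 2]) -
            (tr$b[, 2] - tr$a[, 2]) * (xi - tr$a[, 1])
          d2 <- (tr$c[, 1] - tr$b[, 1]) * (y - tr$b[, 2]) -
            (tr$c[, 2] - tr$b[, 2]) * (xi - tr$b[, 1])
          d3 <- (tr$a[, 1] - tr$c[, 1]) * (y - tr$c[, 2]) -
            (tr$a[, 2] - tr$c[, 2]) * (xi - tr$c[, 1])
          if (any((d1 >= 0 & d2 >= 0 & d3 >= 0) |
                    (d1 <= 0 & d2 <= 0 & d3 <= 0))) cov[j] <- TRUE
        }
      }
      covered <- covered + sum(cov)
    }
  }
  covered / total
}
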
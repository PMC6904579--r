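# Armor assembly: place scale instances into tessellated arrays (uniform
# diamond grid, gradient fan, or curved parametric hosts) and build the
# embedding substrate slab with per-scale sockets.
#
# The diamond lattice is generated by two families of intersecting
# parallel lines whose cell aspect matches the base diamond's W/L; the
# lattice constant is inflated so the nearest base-to-base surface gap
# equals the prescribed inter-scale spacing d.

#' Specify an armor assembly
#'
#' @param pattern `"uniform"`, `"gradient_fan"` or `"on_surface"`.
#' @param params Scale shape, a `scale_params` object (default: the printed
#'   armor-prototype shape, see [prototype_params()]).
#' @param scale_length Base length L of the placed scales, mm; `params` is
#'   rescaled isotropically to this length.
#' @param spacing Inter-scale spacing d (nearest base-to-base surface
#'   distance), mm.
#' @param rows,cols Lattice extent.
#' @param phi Scale orientation angle, degrees in [0, 180): the angle
#'   between the bending/loading direction and the hook direction used by
#'   [bend()].
#' @param substrate_thickness Substrate slab thickness, mm; defaults to the
#'   (scaled) inflection height h1 of the scale.
#' @param fan For `gradient_fan`: list with `origin_a`, `angle_a`,
#'   `dangle_a`, `origin_b`, `angle_b`, `dangle_b` (degrees; a `dangle` of
#'   0 makes that pencil parallel with line spacing `spacing_a`/`spacing_b`).
#'   `NULL` uses a default pair of expanding fans.
#' @param host For `on_surface`: list with `type` in `"plane"`,
#'   `"cylinder"`, `"sphere_cap"` and `radius` (mm) where applicable.
#' @param curvature_coef Size-curvature rule coefficient g: the local scale
#'   length is clamped to g / kappa_max (size factor
#'   min(1, g / (kappa_max * L))).
#' @param resolution Mesh resolution `c(n_sections, n_profile)` for the
#'   placed scale meshes.
#' @return An `assembly_spec` object.
#' @export
assembly_spec <- function(pattern = c("uniform", "gradient_fan", "on_surface"),
                          params = prototype_params(1),
                          scale_length = 10, spacing = 0.5,
                          rows = 7, cols = 7, phi = 0,
                          substrate_thickness = NULL,
                          fan = NULL, host = NULL,
                          curvature_coef = 0.5,
                          resolution = c(40, 40)) {
  pattern <- match.arg(pattern)
  if (scale_length <= 0) abort_validation("scale_length must be > 0")
  if (spacing < 0) abort_validation("spacing d must be >= 0")
  if (spacing / scale_length >= 1)
    abort_validation("spacing must satisfy d/L < 1")
  if (phi < 0 || phi >= 180) abort_validation("phi must lie in [0, 180)")
  if (rows < 1 || cols < 1) abort_validation("rows and cols must be >= 1")
  p <- scale_params_scale(params, scale_length / params$length)
  h_sub <- if (is.null(substrate_thickness)) p$h1 else substrate_thickness
  if (h_sub <= 0) abort_validation("substrate thickness must be > 0")
  structure(list(pattern = pattern, params = p, L = scale_length,
                 d = spacing, rows = rows, cols = cols, phi = phi,
                 h_sub = h_sub, fan = fan, host = host,
                 curvature_coef = curvature_coef,
                 resolution = resolution),
            class = "assembly_spec")
}

# lattice constants: gap-inflated diamond grid. The facing base edges are
# the straight flanks of the (fillet-compensated) base contour; the pitch
# inflation is chosen so their surface-to-surface distance equals d.
lattice_pitch <- function(spec) {
  W <- spec$params$width; L <- spec$L; d <- spec$d
  pf <- base_prefillet(spec$params)
  Wv <- unname(pf["Wv"]); Lv <- unname(pf["Lv"])
  q <- (W / 2) / Wv + (L / 2) / Lv
  kap <- (2 + d * sqrt(1 / Wv^2 + 1 / Lv^2)) / q
  c(sx = kap * W, sy = kap * L)
}

lattice_sites <- function(spec) {
  pit <- lattice_pitch(spec)
  out <- list()
  id <- 0L
  for (j in seq_len(spec$rows) - 1L) {
    for (i in seq_len(spec$cols) - 1L) {
      id <- id + 1L
      out[[id]] <- c(id = id, i = i, j = j,
                     x = pit["sx"] * (i + (j %% 2) / 2),
                     y = pit["sy"] * j / 2)
    }
  }
  sites <- do.call(rbind, out)
  colnames(sites) <- c("id", "i", "j", "x", "y")
  # centre the panel on the origin
  sites[, "x"] <- sites[, "x"] - mean(range(sites[, "x"]))
  sites[, "y"] <- sites[, "y"] - mean(range(sites[, "y"]))
  sites
}

# neighbour classification from lattice offsets
lattice_edges <- function(sites, pitch, tol = 1e-6) {
  n <- nrow(sites)
  edges <- list()
  k <- 0L
  for (a in seq_len(n - 1)) {
    dx <- sites[(a + 1):n, "x"] - sites[a, "x"]
    dy <- sites[(a + 1):n, "y"] - sites[a, "y"]
    cls <- rep(NA_character_, length(dx))
    near <- function(u, v) abs(u - v) < tol * pitch["sx"]
    cls[near(abs(dx), pitch["sx"] / 2) & near(abs(dy), pitch["sy"] / 2)] <- "diagonal"
    cls[near(abs(dx), 0) & near(abs(dy), pitch["sy"])] <- "hook_row"
    cls[near(abs(dx), pitch["sx"]) & near(abs(dy), 0)] <- "same_row"
    for (m in which(!is.na(cls))) {
      k <- k + 1L
      edges[[k]] <- data.frame(a = sites[a, "id"],
                               b = sites[a + m, "id"],
                               class = cls[m])
    }
  }
  if (!k) return(data.frame(a = integer(0), b = integer(0),
                            class = character(0)))
  do.call(rbind, edges)
}

new_assembly <- function(spec, placements, lattice, pitch, template) {
  structure(list(spec = spec, placements = placements, lattice = lattice,
                 pitch = pitch, template = template),
            class = "armor_assembly")
}

#' @export
print.armor_assembly <- function(x, ...) {
  cat(sprintf("armor_assembly: %s pattern, %d scales (L = %g mm, d = %g mm)\n",
              x$spec$pattern, length(x$placements), x$spec$L, x$spec$d))
  invisible(x)
}

#' Tile identical scales into a uniform diamond-grid armor panel
#'
#' Scale bases form a diamond lattice generated by two families of
#' intersecting parallel lines; the lattice constant is chosen so the
#' nearest base-to-base gap equals the spacing d, all hooks co-oriented
#' along +y.
#'
#' @param spec An `assembly_spec` with pattern `"uniform"`.
#' @return An `armor_assembly`.
#' @examples
#' asm <- tile_uniform(assembly_spec(rows = 3, cols = 3,
#'                                   resolution = c(16, 16)))
#' @export
tile_uniform <- function(spec) {
  if (spec$pattern != "uniform")
    abort_validation("spec pattern must be 'uniform'")
  sites <- lattice_sites(spec)
  pitch <- lattice_pitch(spec)
  template <- loft_scale(spec$params, spec$resolution[1], spec$resolution[2])
  placements <- lapply(seq_len(nrow(sites)), function(k) {
    list(id = as.integer(sites[k, "id"]),
         i = as.integer(sites[k, "i"]), j = as.integer(sites[k, "j"]),
         rotation = diag(3),
         translation = unname(c(sites[k, "x"], sites[k, "y"], 0)),
         size = 1)
  })
  lat <- lattice_edges(sites, pitch)
  new_assembly(spec, placements, lat, pitch, template)
}

# pencil line k: point + unit direction
fan_line <- function(fan_half, k) {
  if (fan_half$dangle == 0) {
    th <- fan_half$angle * pi / 180
    u <- c(cos(th), sin(th))
    nrm <- c(-u[2], u[1])
    list(p = fan_half$origin + k * fan_half$spacing * nrm, u = u)
  } else {
    th <- (fan_half$angle + k * fan_half$dangle) * pi / 180
    list(p = fan_half$origin, u = c(cos(th), sin(th)))
  }
}

line_intersect <- function(l1, l2) {
  A <- cbind(l1$u, -l2$u)
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det) < 1e-12) return(c(NA, NA))
  t <- solve(A, l2$p - l1$p)
  l1$p + t[1] * l1$u
}

default_gradient_fan <- function(spec) {
  pit <- lattice_pitch(spec)
  D <- 6 * spec$rows * pit["sy"]                  # fan origins far distal
  gam <- atan2(pit["sx"] / 2, pit["sy"] / 2) * 180 / pi
  dang <- atan2(pit["sx"] / 2, D) * 180 / pi      # ~one cell per step
  list(origin_a = c(-pit["sx"] / 4, D), angle_a = -90 - gam, dangle_a = dang,
       origin_b = c(pit["sx"] / 4, D), angle_b = -90 + gam, dangle_b = -dang)
}

#' Tile scales with a size gradient from two expanding fan grids
#'
#' Scale centres sit at the intersection points of two pencils of lines;
#' each scale's size factor is proportional to the square root of its
#' local cell area, so the scale size shrinks smoothly toward the fan
#' origins (the distal margin), emulating the proximal-to-distal size
#' gradient of the natural girdle.
#'
#' @param spec An `assembly_spec` with pattern `"gradient_fan"`; `spec$fan`
#'   may override the default fan pair (see [assembly_spec()]).
#' @return An `armor_assembly` (placements carry per-scale size factors).
#' @export
tile_gradient_fan <- function(spec) {
  if (spec$pattern != "gradient_fan")
    abort_validation("spec pattern must be 'gradient_fan'")
  fan <- if (is.null(spec$fan)) default_gradient_fan(spec) else spec$fan
  fa <- list(origin = fan$origin_a, angle = fan$angle_a,
             dangle = fan$dangle_a,
             spacing = if (!is.null(fan$spacing_a)) fan$spacing_a else
               lattice_pitch(spec)["sx"] / 2)
  fb <- list(origin = fan$origin_b, angle = fan$angle_b,
             dangle = fan$dangle_b,
             spacing = if (!is.null(fan$spacing_b)) fan$spacing_b else
               lattice_pitch(spec)["sy"] / 2)
  if (fa$dangle != 0 && fb$dangle != 0 &&
      sqrt(sum((fan$origin_a - fan$origin_b)^2)) < 1e-9)
    abort_validation("degenerate fans: coincident origins")
  ni <- spec$cols; nj <- spec$rows
  # node grid (ni+1) x (nj+1) to form ni x nj cells
  nodes <- array(NA_real_, c(ni + 1, nj + 1, 2))
  for (i in 0:ni) for (j in 0:nj)
    nodes[i + 1, j + 1, ] <- line_intersect(fan_line(fa, i), fan_line(fb, j))
  if (anyNA(nodes)) abort_geometry("fan pencils contain parallel line pairs")
  cell_area <- matrix(0, ni, nj)
  for (i in seq_len(ni)) for (j in seq_len(nj)) {
    q <- rbind(nodes[i, j, ], nodes[i + 1, j, ],
               nodes[i + 1, j + 1, ], nodes[i, j + 1, ])
    cell_area[i, j] <- abs(poly_moments(q)$area)
  }
  a_ref <- max(cell_area)
  template <- loft_scale(spec$params, spec$resolution[1], spec$resolution[2])
  placements <- list()
  id <- 0L
  for (i in seq_len(ni)) for (j in seq_len(nj)) {
    id <- id + 1L
    ctr <- (nodes[i, j, ] + nodes[i + 1, j, ] + nodes[i + 1, j + 1, ] +
              nodes[i, j + 1, ]) / 4
    size <- sqrt(cell_area[i, j] / a_ref)
    # hook points away from the fan origins (proximal direction)
    la <- fan_line(fa, i - 1)$u; lb <- fan_line(fb, j - 1)$u
    dir <- la + lb
    if (sum(dir * (colMeans(rbind(fan$origin_a, fan$origin_b)) - ctr)) > 0)
      dir <- -dir
    dir <- dir / sqrt(sum(dir^2))
    ang <- atan2(dir[2], dir[1]) - pi / 2   # rotate +y onto dir
    R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
               c(0, 0, 1))
    placements[[id]] <- list(id = id, i = i - 1L, j = j - 1L,
                             rotation = R,
                             translation = c(ctr[1], ctr[2], 0),
                             size = size,
                             cell_area = cell_area[i, j])
  }
  # label rows proximal-to-distal: row 0 carries the largest scales
  mean_last <- mean(vapply(placements, function(p)
    if (p$j == nj - 1L) p$size else NA_real_, 0), na.rm = TRUE)
  mean_first <- mean(vapply(placements, function(p)
    if (p$j == 0L) p$size else NA_real_, 0), na.rm = TRUE)
  if (mean_last > mean_first)
    placements <- lapply(placements, function(p) {
      p$j <- nj - 1L - p$j
      p
    })
  new_assembly(spec, placements, NULL, lattice_pitch(spec), template)
}

host_geometry <- function(host) {
  type <- host$type
  if (type == "plane") {
    list(map = function(u, v) c(u, v, 0),
         frame = function(u, v) diag(3),
         kmax = function(u, v) 0)
  } else if (type == "cylinder") {
    R <- host$radius
    list(map = function(u, v) c(u, R * sin(v / R), R * cos(v / R) - R),
         frame = function(u, v) {
           yl <- c(0, cos(v / R), -sin(v / R))
           zl <- c(0, sin(v / R), cos(v / R))
           cbind(c(1, 0, 0), yl, zl)
         },
         kmax = function(u, v) 1 / R)
  } else if (type == "sphere_cap") {
    R <- host$radius
    list(map = function(u, v) {
      rho <- sqrt(u^2 + v^2)
      th <- rho / R
      psi <- atan2(v, u)
      c(R * sin(th) * cos(psi), R * sin(th) * sin(psi), R * cos(th) - R)
    },
    frame = function(u, v) {
      rho <- sqrt(u^2 + v^2)
      th <- rho / R
      psi <- if (rho > 1e-12) atan2(v, u) else pi / 2
      zl <- c(sin(th) * cos(psi), sin(th) * sin(psi), cos(th))
      # tangent along increasing v (approximately the hook direction)
      e_th <- c(cos(th) * cos(psi), cos(th) * sin(psi), -sin(th))
      e_ps <- c(-sin(psi), cos(psi), 0)
      yl <- if (rho > 1e-12) e_th * (v / rho) + e_ps * (u / rho) else c(0, 1, 0)
      yl <- yl - sum(yl * zl) * zl
      yl <- yl / sqrt(sum(yl^2))
      xl <- c(yl[2] * zl[3] - yl[3] * zl[2],
              yl[3] * zl[1] - yl[1] * zl[3],
              yl[1] * zl[2] - yl[2] * zl[1])
      cbind(xl, yl, zl)
    },
    kmax = function(u, v) 1 / R)
  } else abort_validation(paste0("unknown host type '", type, "'"))
}

#' Tile scales over a curved host surface
#'
#' Lattice sites are generated in the host's parameter plane and mapped
#' onto the surface; each scale's local frame aligns its dorsal +z with
#' the surface normal and its hook +y with the tangent field, and its size
#' factor follows the inverse-curvature clamp
#' `min(1, g / (kappa_max * L))`.
#'
#' @param spec An `assembly_spec` with pattern `"on_surface"` and a `host`
#'   (plane, cylinder, or sphere_cap).
#' @return An `armor_assembly`.
#' @export
tile_on_surface <- function(spec) {
  if (spec$pattern != "on_surface")
    abort_validation("spec pattern must be 'on_surface'")
  host <- spec$host
  if (is.null(host)) abort_validation("on_surface pattern requires a host")
  geo <- host_geometry(host)
  flat <- spec
  flat$pattern <- "uniform"
  sites <- lattice_sites(flat)
  if (!is.null(host$radius) &&
      host$type == "sphere_cap") {
    span <- max(abs(sites[, c("x", "y")]))
    if (span / host$radius > pi / 2)
      abort_validation("host sphere cap too small for the requested grid")
  }
  template <- loft_scale(spec$params, spec$resolution[1], spec$resolution[2])
  placements <- lapply(seq_len(nrow(sites)), function(k) {
    u <- sites[k, "x"]; v <- sites[k, "y"]
    Fm <- geo$frame(u, v)
    km <- geo$kmax(u, v)
    size <- min(1, spec$curvature_coef / max(km * spec$L, 1e-12))
    list(id = as.integer(sites[k, "id"]),
         i = as.integer(sites[k, "i"]), j = as.integer(sites[k, "j"]),
         rotation = Fm, translation = unname(geo$map(u, v)), size = size)
  })
  lat <- lattice_edges(sites, lattice_pitch(spec))
  new_assembly(spec, placements, lat, lattice_pitch(spec), template)
}

#' Mesh of one placed scale instance
#'
#' @param assembly An `armor_assembly`.
#' @param id Placement id.
#' @return The transformed `scale_mesh`.
#' @export
placed_scale_mesh <- function(assembly, id) {
  pl <- assembly$placements[[id]]
  m <- assembly$template
  if (pl$size != 1) m$vertices <- m$vertices * pl$size
  mesh_transform(m, pl$rotation, pl$translation)
}

#' Build the substrate slab with per-scale sockets
#'
#' The substrate is a slab of the spec's thickness (default: the scale's
#' inflection height h1) whose sockets receive the embedded scale bases.
#' It is built constructively, one lattice cell at a time, as the prism
#' between the cell diamond and the (sheared) base contour — exact for
#' prismatic bases, no mesh booleans required. Supported for flat uniform
#' assemblies.
#'
#' @param assembly A uniform-pattern `armor_assembly`.
#' @param n_ring Sampling resolution of cell and socket rings.
#' @return List with `mesh` (watertight multi-cell substrate), `thickness`,
#'   `volume` (slab minus embedded base volumes, by cross-section
#'   integration of the scale solid), and `footprint_area`.
#' @export
build_substrate <- function(assembly, n_ring = 64) {
  spec <- assembly$spec
  if (spec$pattern != "uniform")
    abort_geometry("substrate generation is supported for uniform flat assemblies")
  h <- spec$h_sub
  pit <- assembly$pitch
  p <- spec$params
  if (!length(assembly$placements)) {
    # no scales: a plain slab covering the nominal grid footprint
    hx <- spec$cols * pit["sx"] / 2; hy <- spec$rows * pit["sy"] / 4
    slab <- extrude_polygon(cbind(c(-hx, hx, hx, -hx), c(-hy, -hy, hy, hy)), h)
    return(list(mesh = slab, thickness = h, volume = unname(4 * hx * hy * h),
                footprint_area = unname(4 * hx * hy), embedded_per_scale = 0))
  }
  shear <- c(0, p$setback_post / p$h1)
  socket <- base_contour(p, n = n_ring)
  # cell diamond sampled at matching angular stations
  th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  cellpoly <- cbind(0.5 * pit["sx"], 0.5 * pit["sy"]) # half extents
  cell <- t(vapply(th, function(a) {
    # radial point on the diamond |x|/hx + |y|/hy = 1
    u <- c(cos(a), sin(a))
    r <- 1 / (abs(u[1]) / (0.5 * pit["sx"]) + abs(u[2]) / (0.5 * pit["sy"]))
    r * u
  }, c(0, 0)))
  cells <- lapply(assembly$placements, function(pl) {
    ctr <- pl$translation[1:2]
    outer_b <- sweep(cell, 2, ctr, `+`)
    inner_b <- sweep(socket, 2, ctr, `+`)
    outer_t <- cbind(outer_b[, 1], outer_b[, 2])
    inner_t <- sweep(inner_b, 2, shear * h, `+`)
    k <- seq_len(n_ring); k2 <- k %% n_ring + 1L
    v <- rbind(cbind(outer_b, 0), cbind(inner_b, 0),
               cbind(outer_t, h), cbind(inner_t, h))
    iob <- k; iib <- n_ring + k; iot <- 2L * n_ring + k; iit <- 3L * n_ring + k
    quad <- function(a, b, c, d) rbind(cbind(a, b, c), cbind(a, c, d))
    faces <- rbind(
      quad(iob[k], iob[k2], iib[k2], iib[k]),   # bottom annulus
      quad(iob[k2], iob[k], iot[k], iot[k2]),   # outer wall
      quad(iot[k2], iot[k], iit[k], iit[k2]),   # top annulus
      quad(iib[k], iib[k2], iit[k2], iit[k]))   # socket wall
    m <- scale_mesh(v, faces, provenance = "external")
    if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
    m
  })
  mesh <- mesh_merge(cells)
  # analytic volume: slab minus the embedded cross-sections of each scale
  nz <- 40
  zs <- (seq_len(nz) - 0.5) * h / nz
  emb <- sum(vapply(zs, function(z)
    mesh_section_area(assembly$template, 3, z), 0)) * h / nz
  cell_a <- pit["sx"] * pit["sy"] / 2
  n_sc <- length(assembly$placements)
  vol <- n_sc * cell_a * h - n_sc * emb
  list(mesh = mesh, thickness = h, volume = unname(vol),
       footprint_area = unname(n_sc * cell_a),
       embedded_per_scale = emb)
}
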
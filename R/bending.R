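# Rigid-scale bending kinematics: wrap the substrate midsurface
# isometrically onto a cylinder of prescribed curvature, carry each rigid
# scale with the local frame of its base site, and detect scale-scale
# contacts. Concave bending (positive curvature, scales facing inward)
# permits geometric interlocking; convex bending leaves the scales free.
#
# The orientation angle phi (degrees) is the angle between the bending
# (curl) direction and the scale width axis: at phi = 0 the panel curls
# along the hook direction (+y); at phi = 90 it curls along the width (x).

curl_direction <- function(phi) {
  a <- phi * pi / 180
  c(sin(a), cos(a))   # phi = 0 -> +y (hook direction), phi = 90 -> +x
}

#' Bend an assembly to uniform curvature
#'
#' Maps the substrate midsurface isometrically onto a cylinder of radius
#' 1/|kappa| whose axis is perpendicular to the curl direction, and carries
#' each rigid scale by the rigid transform of its base site. Positive
#' kappa is concave (scales facing inward / toward each other); negative
#' kappa is convex.
#'
#' @param assembly A flat `armor_assembly` (uniform or gradient pattern).
#' @param phi Orientation angle, degrees in [0, 180).
#' @param kappa Signed curvature, 1/mm.
#' @return A `bend_state`: the assembly plus per-scale bent transforms and
#'   the bending parameters.
#' @examples
#' asm <- tile_uniform(assembly_spec(rows = 3, cols = 3,
#'                                   resolution = c(16, 16)))
#' st <- bend(asm, phi = 90, kappa = 0.01)
#' @export
bend <- function(assembly, phi, kappa) {
  if (phi < 0 || phi >= 180) abort_validation("phi must lie in [0, 180)")
  u2 <- curl_direction(phi)
  spans <- vapply(assembly$placements, function(p)
    sum(p$translation[1:2] * u2), 0)
  half_span <- max(abs(spans))
  if (abs(kappa) * half_span >= pi)
    abort_geometry("over-curvature: |kappa| * half-span must be < pi")
  z_mid <- assembly$spec$h_sub / 2
  u3 <- c(u2, 0)
  a3 <- c(u2[2], -u2[1], 0)     # cylinder axis (in-plane, perp to curl)
  placements <- lapply(assembly$placements, function(p) {
    s <- sum(p$translation[1:2] * u2)
    t <- sum(p$translation[1:2] * a3[1:2])
    if (kappa == 0) {
      q <- p
      q$bent_rotation <- diag(3)
      q$bent_translation <- c(0, 0, 0)
      return(q)
    }
    rho <- 1 / kappa
    psi <- s * kappa
    # wrapped position of the site's midsurface point
    wrapped <- a3 * t + u3 * (rho * sin(psi)) +
      c(0, 0, z_mid + rho * (1 - cos(psi)))
    # rotation by psi about the axis a3 (turning u3 toward +z)
    R <- rot_about_axis(a3, psi, u3)
    site_mid <- c(p$translation[1:2], z_mid)
    q <- p
    q$bent_rotation <- R
    q$bent_translation <- wrapped - as.vector(R %*% site_mid)
    q
  })
  structure(list(assembly = assembly, phi = phi, kappa = kappa,
                 placements = placements),
            class = "bend_state")
}

# rotation about unit axis a by angle psi, with the sign fixed so that the
# curl direction u3 rotates toward +z for positive psi
rot_about_axis <- function(a, psi, u3) {
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  R <- diag(3) + sin(psi) * K + (1 - cos(psi)) * (K %*% K)
  # check handedness: u3 should acquire a +z component for psi > 0
  if (psi != 0 && (R %*% u3)[3] * sin(psi) < 0) {
    R <- diag(3) - sin(psi) * K + (1 - cos(psi)) * (K %*% K)
  }
  R
}

#' @export
print.bend_state <- function(x, ...) {
  cat(sprintf("bend_state: phi = %g deg, kappa = %g 1/mm (%s)\n",
              x$phi, x$kappa,
              if (x$kappa > 0) "concave" else if (x$kappa < 0) "convex"
              else "flat"))
  invisible(x)
}

bent_scale_mesh <- function(state, id) {
  pl <- state$placements[[id]]
  m <- state$assembly$template
  if (pl$size != 1) m$vertices <- m$vertices * pl$size
  m <- mesh_transform(m, pl$rotation, pl$translation)
  mesh_transform(m, pl$bent_rotation, pl$bent_translation)
}

#' Detect scale-scale contacts in a bent state
#'
#' An edge joins every pair of scales whose surface-to-surface distance is
#' below the tolerance; edges carry witness points and the lattice
#' neighbour class (`diagonal`, `hook_row`, `same_row`, or `other`).
#'
#' @param state A `bend_state`.
#' @param tolerance Contact distance threshold, mm; defaults to 5% of the
#'   inter-scale spacing d.
#' @param ids Optional subset of placement ids to restrict the query to
#'   (pairs with at least one member in `ids`).
#' @param first_only Stop at the first contacting pair (for onset search).
#' @return A data frame (`contact_graph`) with columns a, b, distance,
#'   class and witness coordinates; zero rows if no contacts.
#' @export
detect_contacts <- function(state, tolerance = NULL, ids = NULL,
                            first_only = FALSE) {
  asm <- state$assembly
  if (is.null(tolerance)) tolerance <- 0.05 * asm$spec$d
  n <- length(state$placements)
  meshes <- vector("list", n)
  getm <- function(k) {
    if (is.null(meshes[[k]])) meshes[[k]] <<- bent_scale_mesh(state, k)
    meshes[[k]]
  }
  boxes <- lapply(seq_len(n), function(k) mesh_bbox(getm(k)))
  cls_lookup <- new.env()
  if (!is.null(asm$lattice) && nrow(asm$lattice))
    for (r in seq_len(nrow(asm$lattice)))
      assign(paste(asm$lattice$a[r], asm$lattice$b[r]),
             asm$lattice$class[r], envir = cls_lookup)
  res <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (!is.null(ids) && !(a %in% ids) && !(b %in% ids)) next
      gap <- pmax(0, pmax(boxes[[a]][1, ] - boxes[[b]][2, ],
                          boxes[[b]][1, ] - boxes[[a]][2, ]))
      if (sqrt(sum(gap^2)) > tolerance) next
      md <- mesh_min_distance(getm(a), getm(b), cutoff = tolerance * 4)
      if (is.finite(md$distance) && md$distance < tolerance) {
        key <- paste(a, b)
        cls <- if (exists(key, envir = cls_lookup))
          get(key, envir = cls_lookup) else "other"
        res[[length(res) + 1]] <- data.frame(
          a = a, b = b, distance = md$distance, class = cls,
          px = md$p1[1], py = md$p1[2], pz = md$p1[3],
          qx = md$p2[1], qy = md$p2[2], qz = md$p2[3])
        if (first_only)
          return(do.call(rbind, res))
      }
    }
  }
  if (!length(res))
    return(data.frame(a = integer(0), b = integer(0), distance = numeric(0),
                      class = character(0), px = numeric(0), py = numeric(0),
                      pz = numeric(0), qx = numeric(0), qy = numeric(0),
                      qz = numeric(0)))
  do.call(rbind, res)
}

#' Interior scale ids of a uniform assembly
#'
#' Interior scales are lattice sites with the full 4-diagonal
#' neighbourhood; boundary scales are excluded from per-scale contact
#' counts.
#'
#' @param assembly An `armor_assembly` with a lattice.
#' @return Integer vector of placement ids.
#' @export
interior_ids <- function(assembly) {
  if (is.null(assembly$lattice)) return(integer(0))
  ids <- vapply(assembly$placements, function(p) p$id, 0L)
  ndiag <- vapply(ids, function(id) {
    sum(assembly$lattice$class == "diagonal" &
          (assembly$lattice$a == id | assembly$lattice$b == id))
  }, 0L)
  ids[ndiag == 4L]
}

#' Contact-onset curvature
#'
#' The smallest concave curvature at which the interior contact graph
#' becomes non-empty, located by bisection.
#'
#' @param assembly An `armor_assembly`.
#' @param phi Orientation angle, degrees.
#' @param tolerance Contact distance threshold (see [detect_contacts()]).
#' @param kappa_max Upper end of the search bracket, 1/mm; defaults to 90%
#'   of the over-curvature domain limit.
#' @param tol_kappa Bisection tolerance, 1/mm.
#' @return List with `kappa_star` (NA if no interlocking occurs within the
#'   domain), `first_contact_class`, and the search bracket.
#' @export
onset_curvature <- function(assembly, phi, tolerance = NULL,
                            kappa_max = NULL, tol_kappa = 1e-4) {
  u2 <- curl_direction(phi)
  spans <- vapply(assembly$placements, function(p)
    sum(p$translation[1:2] * u2), 0)
  half_span <- max(abs(spans))
  if (is.null(kappa_max)) kappa_max <- 0.9 * pi / half_span
  ids <- interior_ids(assembly)
  if (!length(ids)) ids <- NULL
  probe <- function(k) {
    st <- bend(assembly, phi, k)
    cg <- detect_contacts(st, tolerance = tolerance, ids = ids,
                          first_only = TRUE)
    if (nrow(cg)) cg else NULL
  }
  hi_contact <- probe(kappa_max)
  if (is.null(hi_contact))
    return(list(kappa_star = NA_real_, first_contact_class = "no interlocking",
                bracket = c(0, kappa_max)))
  lo <- 0; hi <- kappa_max
  witness <- hi_contact
  while (hi - lo > tol_kappa) {
    mid <- (lo + hi) / 2
    cg <- probe(mid)
    if (!is.null(cg)) {
      hi <- mid
      witness <- cg
    } else lo <- mid
  }
  list(kappa_star = hi, first_contact_class = witness$class[1],
       bracket = c(lo, hi))
}
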
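# Structured tetrahedral meshing of the ellipsoidal head.
#
# The unit ball is meshed on a latitude-longitude-radius lattice whose
# azimuthal grid is aligned with the 16 electrode centres and whose
# latitude grid is refined in the band around the electrode-ring latitude;
# radial layers are graded towards the surface. Lattice cells (hexahedra in
# index space; prisms at the two polar caps; pyramids around the centre)
# are split into tetrahedra with the Kuhn convention, which is conforming
# across cells including the azimuthal wrap. The unit ball is then scaled
# componentwise onto the head ellipsoid, so the mesh topology is identical
# for every head variant and electrode patches sit at the same lattice
# positions at every resolution.

# The coarse lattice is the study workhorse; "medium" refines it by nested
# midpoint splits of the radial and latitude grids, and "fine" additionally
# splits the azimuthal grid. Nested refinement keeps electrode patches and
# lattice geometry aligned across presets, so coarse-to-fine channel
# differences measure genuine h-refinement error.
MESH_PRESETS <- list(
  coarse = list(split_theta_u = FALSE, split_phi = FALSE, target_elems = 61000),
  medium = list(split_theta_u = TRUE, split_phi = FALSE, target_elems = 243000),
  fine = list(split_theta_u = TRUE, split_phi = TRUE, target_elems = 486000)
)

BASE_GRID <- list(
  elec_offsets = c(-0.06, 0, 0.06), n_mid = 1L,
  band = c(-0.30, -0.19, -0.11, -0.055, -0.017, 0, 0.017, 0.055, 0.11, 0.19, 0.30),
  n_polar = 4L,
  layers = c(0.22, 0.42, 0.58, 0.72, 0.83, 0.90, 0.95, 0.98, 1)
)

# Azimuthal electrode-centre angles: the parametric angle t of the ring
# ellipse (x = a sin t, y = b cos t) at equal arc-length spacing, which is
# invariant under uniform in-plane scaling and ring height.
electrode_azimuths <- function() {
  a <- BASE_HEAD_SEMI_AXES[1]
  b <- BASE_HEAD_SEMI_AXES[2]
  tt <- seq(0, 2 * pi, length.out = 4097)
  seg <- sqrt((a * diff(sin(tt)))^2 + (b * diff(cos(tt)))^2)
  s <- c(0, cumsum(seg))
  targets <- (seq_len(16) - 0.5) / 16 * s[length(s)]
  approx(s, tt, xout = targets)$y
}

midpoint_split <- function(g) sort(c(g, (g[-1] + g[-length(g)]) / 2))

lat_long_grids <- function(preset) {
  p <- MESH_PRESETS[[preset]]
  if (is.null(p)) abort(paste0("unknown mesh resolution preset '", preset, "'"))
  b <- BASE_GRID
  tk <- electrode_azimuths()
  phi <- c()
  for (k in seq_along(tk)) {
    phi <- c(phi, tk[k] + b$elec_offsets)
    t_next <- if (k < length(tk)) tk[k + 1] else tk[1] + 2 * pi
    gap <- seq(tk[k] + max(b$elec_offsets), t_next + min(b$elec_offsets),
      length.out = b$n_mid + 2L
    )
    phi <- c(phi, gap[-c(1, length(gap))])
  }
  phi <- sort(phi %% (2 * pi))
  # Latitude of the nominal ring plane on the unit sphere.
  theta0 <- acos(BASE_BRAIN_CENTRE_OFFSET / BASE_HEAD_SEMI_AXES[3])
  th_band <- theta0 + b$band
  th_lo <- seq(0.22, min(th_band), length.out = b$n_polar + 1L)
  th_hi <- seq(max(th_band), pi - 0.22, length.out = b$n_polar + 1L)
  theta <- sort(unique(c(th_lo[-length(th_lo)], th_band, th_hi[-1])))
  u <- b$layers
  if (p$split_theta_u) {
    theta <- midpoint_split(theta)
    u <- midpoint_split(c(0, u))
    u <- u[u > 0]
  }
  if (p$split_phi) {
    phi <- sort(c(phi, (c(phi[-1], phi[1] + 2 * pi) + phi) / 2) %% (2 * pi))
  }
  list(u = u, theta = theta, phi = phi)
}

tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE] - a
  c_ <- nodes[elems[, 3], , drop = FALSE] - a
  d <- nodes[elems[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
    b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
    b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

tri_areas <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  u <- nodes[tris[, 2], , drop = FALSE] - a
  v <- nodes[tris[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Faces occurring in exactly one tetrahedron form the boundary.
boundary_faces <- function(elems) {
  f <- rbind(
    elems[, c(1L, 2L, 3L)], elems[, c(1L, 2L, 4L)],
    elems[, c(1L, 3L, 4L)], elems[, c(2L, 3L, 4L)]
  )
  x1 <- pmin(f[, 1], f[, 2], f[, 3])
  x3 <- pmax(f[, 1], f[, 2], f[, 3])
  x2 <- f[, 1] + f[, 2] + f[, 3] - x1 - x3
  o <- order(x1, x2, x3)
  s1 <- x1[o]
  s2 <- x2[o]
  s3 <- x3[o]
  same_prev <- c(FALSE, s1[-1] == s1[-length(s1)] & s2[-1] == s2[-length(s2)] & s3[-1] == s3[-length(s3)])
  same_next <- c(same_prev[-1], FALSE)
  single <- !(same_prev | same_next)
  cbind(s1[o_idx <- which(single)], s2[o_idx], s3[o_idx])
}

unit_ball_mesh <- function(resolution = "coarse") {
  key <- paste0("unit:", resolution)
  if (!is.null(the$meshes[[key]])) {
    return(the$meshes[[key]])
  }
  g <- lat_long_grids(resolution)
  L <- length(g$u)
  J <- length(g$theta)
  N <- length(g$phi)

  # Lattice nodes: id(i, j, k) over phi i, theta ring j, layer k; then a
  # top/bottom pole node per layer and the centre node.
  id <- function(i, j, k) ((i - 1L) %% N) + 1L + (j - 1L) * N + (k - 1L) * N * J
  n_lat <- N * J * L
  pole_t <- function(k) n_lat + k
  pole_b <- function(k) n_lat + L + k
  centre <- n_lat + 2L * L + 1L

  dir <- cbind(
    rep(sin(g$theta), each = N) * sin(g$phi),
    rep(sin(g$theta), each = N) * cos(g$phi),
    rep(cos(g$theta), each = N)
  )
  nodes <- matrix(0, centre, 3L)
  for (k in seq_len(L)) {
    nodes[(k - 1L) * N * J + seq_len(N * J), ] <- g$u[k] * dir
    nodes[pole_t(k), ] <- c(0, 0, g$u[k])
    nodes[pole_b(k), ] <- c(0, 0, -g$u[k])
  }

  # Band hexahedra: Kuhn subdivision in (u, theta, phi) index space. The
  # face diagonals depend only on the in-face index pairs, so the split is
  # conforming across cells and across the azimuthal wrap.
  ci <- rep(seq_len(N), times = (J - 1L) * (L - 1L))
  cj <- rep(rep(seq_len(J - 1L), each = N), times = L - 1L)
  ck <- rep(seq_len(L - 1L), each = N * (J - 1L))
  corner <- function(dk, dj, di) id(ci + di, cj + dj, ck + dk)
  perms <- list(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
  step <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  tets <- vector("list", 8L)
  for (t in seq_along(perms)) {
    p <- perms[[t]]
    d1 <- step[p[1L], ]
    d2 <- d1 + step[p[2L], ]
    tets[[t]] <- cbind(
      corner(0L, 0L, 0L),
      corner(d1[1L], d1[2L], d1[3L]),
      corner(d2[1L], d2[2L], d2[3L]),
      corner(1L, 1L, 1L)
    )
  }

  # Polar caps: triangular prisms between consecutive layers, split into
  # three tetrahedra honouring the Kuhn diagonal on the face shared with
  # the band hexahedra.
  cap_tets <- function(pole, ring_j) {
    out <- vector("list", L - 1L)
    for (k in seq_len(L - 1L)) {
      a_k <- id(seq_len(N), ring_j, k)
      b_k <- id(seq_len(N) + 1L, ring_j, k)
      a_k1 <- id(seq_len(N), ring_j, k + 1L)
      b_k1 <- id(seq_len(N) + 1L, ring_j, k + 1L)
      p_k <- rep(pole(k), N)
      p_k1 <- rep(pole(k + 1L), N)
      out[[k]] <- rbind(
        cbind(p_k, a_k, b_k, b_k1),
        cbind(p_k, a_k, b_k1, a_k1),
        cbind(p_k, a_k1, b_k1, p_k1)
      )
    }
    do.call(rbind, out)
  }
  tets[[7L]] <- rbind(cap_tets(pole_t, 1L), cap_tets(pole_b, J))

  # Innermost shell: pyramids from the layer-1 lattice quads to the centre
  # (diagonal matching the Kuhn diagonal of the layer-1/2 hexahedra), plus
  # polar tetrahedra.
  fi <- rep(seq_len(N), times = J - 1L)
  fj <- rep(seq_len(J - 1L), each = N)
  A <- id(fi, fj, 1L)
  B <- id(fi + 1L, fj, 1L)
  C <- id(fi + 1L, fj + 1L, 1L)
  D <- id(fi, fj + 1L, 1L)
  O <- rep(centre, length(A))
  tets[[8L]] <- rbind(
    cbind(O, A, B, C), cbind(O, A, C, D),
    cbind(rep(centre, N), rep(pole_t(1L), N), id(seq_len(N), 1L, 1L), id(seq_len(N) + 1L, 1L, 1L)),
    cbind(rep(centre, N), rep(pole_b(1L), N), id(seq_len(N), J, 1L), id(seq_len(N) + 1L, J, 1L))
  )

  elems <- do.call(rbind, tets)
  dimnames(elems) <- NULL
  storage.mode(elems) <- "integer"
  vol <- tet_volumes(nodes, elems)
  flip <- vol < 0
  if (any(flip)) elems[flip, 3:4] <- elems[flip, c(4L, 3L)]
  if (any(abs(tet_volumes(nodes, elems)) < 1e-16)) {
    abort("meshing failure: degenerate element in unit ball mesh")
  }
  bf <- boundary_faces(elems)
  m <- list(nodes = nodes, elems = elems, boundary = bf, resolution = resolution)
  the$meshes[[key]] <- m
  m
}

# Fractional patch coverage: each boundary facet contributes to an
# electrode in proportion to the patch weight profile integrated over the
# facet (barycentric quadrature lattice). The contact conductance tapers
# smoothly (raised cosine) from full contact inside 0.7 r to zero at 1.3 r,
# modelling the gel fringe of an EEG-style electrode; a smooth profile also
# makes the effective patch geometry insensitive to the facet layout, so
# refining the mesh does not move the electrodes.
barycentric_lattice <- function(degree = 5L) {
  g <- expand.grid(i = 0:degree, j = 0:degree)
  g <- g[g$i + g$j <= degree, ]
  cbind(g$i, g$j, degree - g$i - g$j) / degree
}

patch_weight_profile <- function(d, radius) {
  r_in <- 0.7 * radius
  r_out <- 1.3 * radius
  w <- 0.5 * (1 + cos(pi * (d - r_in) / (r_out - r_in)))
  w[d <= r_in] <- 1
  w[d >= r_out] <- 0
  w
}

patch_coverage <- function(nodes, faces, areas, centre, radius) {
  lat <- barycentric_lattice()
  cen <- (nodes[faces[, 1], , drop = FALSE] + nodes[faces[, 2], , drop = FALSE] +
    nodes[faces[, 3], , drop = FALSE]) / 3
  d <- sqrt(colSums((t(cen) - centre)^2))
  diam <- sqrt(4 * areas) # facet length-scale bound
  cand <- which(d < 1.3 * radius + diam)
  if (length(cand) == 0L) cand <- which.min(d)
  w <- numeric(length(cand))
  for (q in seq_along(cand)) {
    f <- faces[cand[q], ]
    pts <- lat %*% nodes[f, , drop = FALSE]
    w[q] <- mean(patch_weight_profile(sqrt(colSums((t(pts) - centre)^2)), radius))
  }
  keep <- w > 1e-8
  if (!any(keep)) {
    keep[which.min(d[cand])] <- TRUE
    w[keep] <- 1
  }
  list(faces = cand[keep], weights = w[keep])
}

#' Mesh a head model with electrode patches
#'
#' Builds a tetrahedral mesh of the full head volume by scaling a cached
#' structured unit-ball mesh onto the head ellipsoid, and identifies, for
#' each of the 16 electrodes, the set of boundary facets representing its
#' contact patch (total facet area matched to the nominal patch area
#' `pi r^2`).
#'
#' @param geom An `eit_head_geometry`.
#' @param ring An [electrode_ring_spec()].
#' @param resolution Mesh preset: `"coarse"`, `"medium"` or `"fine"`.
#' @return An object of class `eit_mesh`: node coordinates (m), tetrahedra,
#'   boundary triangles, per-electrode facet-row sets, electrode centres,
#'   element volumes and centroids.
#' @export
build_mesh <- function(geom, ring = electrode_ring_spec(), resolution = "coarse") {
  stopifnot(inherits(geom, "eit_head_geometry"))
  um <- unit_ball_mesh(resolution)
  nodes <- sweep(um$nodes, 2, geom$head_semi_axes, "*")
  vol <- tet_volumes(nodes, um$elems)
  centroids_e <- (nodes[um$elems[, 1], ] + nodes[um$elems[, 2], ] +
    nodes[um$elems[, 3], ] + nodes[um$elems[, 4], ]) / 4

  b <- um$boundary
  areas <- tri_areas(nodes, b)
  centroids_b <- (nodes[b[, 1], ] + nodes[b[, 2], ] + nodes[b[, 3], ]) / 3

  ec <- electrode_positions(geom, ring)
  r_patch <- ring$electrode_radius_mm * 1e-3
  taken <- rep(FALSE, nrow(b))
  elec_faces <- vector("list", ring$n_electrodes)
  elec_weights <- vector("list", ring$n_electrodes)
  for (l in seq_len(ring$n_electrodes)) {
    sel <- patch_coverage(nodes, b, areas, ec[l, ], r_patch)
    if (length(sel$faces) == 0L) abort("meshing failure: empty electrode facet set")
    if (any(taken[sel$faces])) abort("meshing failure: overlapping electrode patches")
    taken[sel$faces] <- TRUE
    elec_faces[[l]] <- sel$faces
    elec_weights[[l]] <- sel$weights
  }

  structure(
    list(
      nodes = nodes, elems = um$elems, boundary = b,
      elec_faces = elec_faces, elec_weights = elec_weights, elec_centres = ec,
      elem_volumes = abs(vol), elem_centroids = centroids_e,
      boundary_areas = areas, ring = ring, resolution = resolution,
      head_semi_axes = geom$head_semi_axes
    ),
    class = "eit_mesh"
  )
}

#' Effective electrode patch areas
#'
#' Coverage-weighted facet area per electrode (before contact-area
#' normalisation in the solver).
#'
#' @param mesh An `eit_mesh`.
#' @return Numeric vector of 16 areas (square metres).
#' @export
electrode_patch_areas <- function(mesh) {
  vapply(seq_along(mesh$elec_faces), function(l) {
    sum(mesh$boundary_areas[mesh$elec_faces[[l]]] * mesh$elec_weights[[l]])
  }, numeric(1))
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf(
    "<eit_mesh> %d nodes, %d tetrahedra, %d boundary facets, %d electrodes (%s preset)\n",
    nrow(x$nodes), nrow(x$elems), nrow(x$boundary), length(x$elec_faces),
    x$resolution
  ))
  invisible(x)
}

#' Assign per-element conductivities
#'
#' Region membership is evaluated at each element centroid: outer shell
#' 0.1 S/m, brain 0.3 S/m, lesion 0.7 S/m.
#'
#' @param mesh An `eit_mesh`.
#' @param geom The `eit_head_geometry` the mesh was built from.
#' @param lesion Optional placed lesion (see [place_lesion()]).
#' @param conductivities Named vector of tissue conductivities (S/m).
#' @return Numeric vector of per-element conductivities (S/m).
#' @export
assign_conductivity <- function(mesh, geom, lesion = NULL,
                                conductivities = c(outer = 0.1, brain = 0.3, lesion = 0.7)) {
  region <- region_membership(geom, mesh$elem_centroids, lesion)
  unname(conductivities[region])
}
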
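# Complete-electrode-model (CEM) forward solver.
#
# Solves div(sigma grad u) = 0 in the head with CEM boundary conditions:
# on each electrode patch E_l with contact impedance z,
#   u + z sigma du/dn = U_l on E_l,   integral_{E_l} sigma du/dn dS = I_l,
# and zero current flux elsewhere. Discretised with linear tetrahedral
# elements; the coupled (u, U) system is symmetric positive definite once
# one electrode potential is grounded, and is factorised once per
# conductivity map with all 16 injections solved together.

#' Build a skip-s stimulation/measurement pattern
#'
#' Injection pairs are `(i, i + skip + 1)` (mod n) for i = 1..n in order; for
#' each injection, measurement pairs `(m, m + skip + 1)` are emitted with m
#' ascending, excluding any pair that contains an injecting electrode.
#' Channel order is injection-major, measurement-minor. For 16 electrodes
#' and skip 2 this yields the conventional 208-channel frame.
#'
#' @param n_electrodes Number of electrodes (>= skip + 4).
#' @param skip Number of electrodes skipped between pair members.
#' @return An object of class `eit_stim_pattern`: a tibble with columns
#'   `channel`, `inj_pos`, `inj_neg`, `meas_pos`, `meas_neg`, plus attributes
#'   `n_electrodes`, `skip`.
#' @export
build_stim_pattern <- function(n_electrodes = 16, skip = 2) {
  n <- as.integer(n_electrodes)
  s <- as.integer(skip)
  if (n < s + 4L) abort("n_electrodes must be at least skip + 4")
  wrap <- function(x) ((x - 1L) %% n) + 1L
  rows <- list()
  for (i in seq_len(n)) {
    ip <- i
    im <- wrap(i + s + 1L)
    for (m in seq_len(n)) {
      mp <- m
      mm <- wrap(m + s + 1L)
      if (any(c(mp, mm) %in% c(ip, im))) next
      rows[[length(rows) + 1L]] <- c(ip, im, mp, mm)
    }
  }
  q <- do.call(rbind, rows)
  out <- tibble(
    channel = seq_len(nrow(q)),
    inj_pos = q[, 1], inj_neg = q[, 2],
    meas_pos = q[, 3], meas_neg = q[, 4]
  )
  attr(out, "n_electrodes") <- n
  attr(out, "skip") <- s
  class(out) <- c("eit_stim_pattern", class(out))
  out
}

# Per-element 4x4 stiffness contributions for unit conductivity, as triplet
# arrays (16 entries per tetrahedron), vectorised over all elements.
element_stiffness_triplets <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  e1 <- nodes[elems[, 2], , drop = FALSE] - p1
  e2 <- nodes[elems[, 3], , drop = FALSE] - p1
  e3 <- nodes[elems[, 4], , drop = FALSE] - p1
  cross <- function(a, b) {
    cbind(
      a[, 2] * b[, 3] - a[, 3] * b[, 2],
      a[, 3] * b[, 1] - a[, 1] * b[, 3],
      a[, 1] * b[, 2] - a[, 2] * b[, 1]
    )
  }
  c23 <- cross(e2, e3)
  det <- rowSums(e1 * c23) # 6 V (signed; orientation fixed at mesh build)
  vol <- abs(det) / 6
  # Gradients of barycentric functions 2..4 are rows of inv([e1;e2;e3]):
  g2 <- c23 / det
  g3 <- cross(e3, e1) / det
  g4 <- cross(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  gl <- list(g1, g2, g3, g4)
  ne <- nrow(elems)
  ii <- matrix(0L, ne, 16L)
  jj <- matrix(0L, ne, 16L)
  kk <- matrix(0, ne, 16L)
  idx <- 1L
  for (a in 1:4) {
    for (b in 1:4) {
      ii[, idx] <- elems[, a]
      jj[, idx] <- elems[, b]
      kk[, idx] <- vol * rowSums(gl[[a]] * gl[[b]])
      idx <- idx + 1L
    }
  }
  list(i = as.vector(ii), j = as.vector(jj), k = as.vector(kk), elem = rep(seq_len(ne), 16L))
}

# Electrode boundary integrals (independent of the conductivity map).
# Contact areas are normalised so each electrode's effective area is exactly
# pi r^2, keeping the effective contact geometry consistent across mesh
# resolutions.
electrode_boundary_terms <- function(mesh, normalise_contact = TRUE) {
  z <- mesh$ring$contact_impedance
  nL <- length(mesh$elec_faces)
  n <- nrow(mesh$nodes)
  target <- pi * (mesh$ring$electrode_radius_mm * 1e-3)^2
  zi <- zj <- integer(0)
  zv <- numeric(0)
  vi <- vl <- integer(0)
  vv <- numeric(0)
  dv <- numeric(nL)
  for (l in seq_len(nL)) {
    tris <- mesh$boundary[mesh$elec_faces[[l]], , drop = FALSE]
    ar <- mesh$boundary_areas[mesh$elec_faces[[l]]] * mesh$elec_weights[[l]]
    beta <- if (normalise_contact) target / sum(ar) else 1
    ar <- ar * beta
    # Triangle mass matrix: A/6 diagonal, A/12 off-diagonal.
    for (a in 1:3) {
      for (b in 1:3) {
        zi <- c(zi, tris[, a])
        zj <- c(zj, tris[, b])
        zv <- c(zv, ar * (if (a == b) 1 / 6 else 1 / 12) / z)
      }
      vi <- c(vi, tris[, a])
      vl <- c(vl, rep(l, nrow(tris)))
      vv <- c(vv, ar / 3 / z)
    }
    dv[l] <- sum(ar) / z
  }
  list(
    Z = Matrix::sparseMatrix(i = zi, j = zj, x = zv, dims = c(n, n)),
    V = Matrix::sparseMatrix(i = vi, j = vl, x = vv, dims = c(n, nL)),
    D = dv
  )
}

#' Precompute the resolution- and geometry-dependent parts of the forward map
#'
#' The returned operator can be re-assembled cheaply for any conductivity
#' map on the same mesh (one sparse Cholesky factorisation per map).
#'
#' @param mesh An `eit_mesh`.
#' @return An object of class `eit_forward_operator`.
#' @export
forward_operator <- function(mesh) {
  trip <- element_stiffness_triplets(mesh$nodes, mesh$elems)
  bt <- electrode_boundary_terms(mesh)
  structure(
    list(
      mesh = mesh, trip = trip, bt = bt, n_nodes = nrow(mesh$nodes),
      env = new.env(parent = emptyenv()) # caches the symbolic factorisation
    ),
    class = "eit_forward_operator"
  )
}

#' Solve the CEM forward problem for one conductivity map
#'
#' @param mesh An `eit_mesh`, or an `eit_forward_operator` built from one
#'   (reusing an operator across conductivity maps avoids re-deriving the
#'   element matrices).
#' @param sigma Per-element conductivities (S/m), as from
#'   [assign_conductivity()].
#' @param ring Electrode ring spec; defaults to the one stored in the mesh.
#' @param pattern An [build_stim_pattern()] pattern.
#' @return An object of class `eit_frame_raw`: a numeric vector of channel
#'   voltage magnitudes (V) with the pattern and electrode potentials in
#'   attributes.
#' @export
solve_forward <- function(mesh, sigma, ring = NULL,
                          pattern = build_stim_pattern(16, 2)) {
  op <- if (inherits(mesh, "eit_forward_operator")) mesh else forward_operator(mesh)
  mesh <- op$mesh
  ring <- ring %||% mesh$ring
  if (length(sigma) != nrow(mesh$elems)) {
    abort("sigma must have one value per mesh element")
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("conductivities must be finite and strictly positive")
  }
  nL <- length(mesh$elec_faces)
  n <- op$n_nodes

  Ann <- Matrix::sparseMatrix(
    i = op$trip$i, j = op$trip$j,
    x = op$trip$k * sigma[op$trip$elem], dims = c(n, n)
  ) + op$bt$Z
  # Ground electrode nL (drop its potential DOF); measurements are voltage
  # differences, so the reference is immaterial.
  keep <- seq_len(nL - 1L)
  A <- rbind(
    cbind(Ann, -op$bt$V[, keep, drop = FALSE]),
    cbind(Matrix::t(-op$bt$V[, keep, drop = FALSE]),
          Matrix::Diagonal(nL - 1L, op$bt$D[keep]))
  )
  inj <- unique(pattern[, c("inj_pos", "inj_neg")])
  B <- matrix(0, n + nL - 1L, nrow(inj))
  for (q in seq_len(nrow(inj))) {
    ip <- inj$inj_pos[q]
    im <- inj$inj_neg[q]
    if (ip < nL) B[n + ip, q] <- ring$current_a
    if (im < nL) B[n + im, q] <- B[n + im, q] - ring$current_a
  }
  A <- Matrix::forceSymmetric(A)
  X <- tryCatch(
    {
      # The sparsity pattern is fixed per operator, so the symbolic analysis
      # is reused across conductivity maps.
      ch <- if (is.null(op$env$factor)) {
        op$env$factor <- Matrix::Cholesky(A, super = TRUE)
      } else {
        Matrix::update(op$env$factor, A)
      }
      as.matrix(Matrix::solve(ch, B))
    },
    error = function(e) {
      abort(paste0("forward solver failure (singular or indefinite system): ",
                   conditionMessage(e)))
    }
  )
  U <- rbind(X[n + seq_len(nL - 1L), , drop = FALSE], 0) # nL x n_inj

  inj_key <- paste(inj$inj_pos, inj$inj_neg)
  col <- match(paste(pattern$inj_pos, pattern$inj_neg), inj_key)
  v <- abs(U[cbind(pattern$meas_pos, col)] - U[cbind(pattern$meas_neg, col)])
  structure(v,
    pattern = pattern, electrode_potentials = U,
    class = "eit_frame_raw"
  )
}

#' Simulate the noiseless measurement frame for one model descriptor
#'
#' Builds geometry, mesh and conductivity map for a model-grid descriptor row
#' and solves the forward problem. Results are cached per (descriptor,
#' resolution) for the session, since they are deterministic.
#'
#' @param descriptor A single row of [enumerate_models()].
#' @param resolution Mesh preset.
#' @param cache Use the session cache (default `TRUE`).
#' @return Numeric vector of 208 channel voltage magnitudes (V).
#' @export
simulate_frame <- function(descriptor, resolution = "coarse", cache = TRUE) {
  key <- paste0(descriptor$model_id, "|", resolution)
  if (cache && !is.null(the$frames[[key]])) {
    return(the$frames[[key]])
  }
  mdl <- build_model(descriptor)
  # Operators depend only on the head shape and ring height (the brain and
  # lesion enter through the conductivity map), so they are shared across
  # all models with the same outer boundary.
  op_key <- paste0(
    "op:", paste(signif(mdl$geom$head_semi_axes, 10), collapse = ","),
    "|z=", mdl$ring$height_offset_mm, "|", resolution
  )
  op <- the$meshes[[op_key]]
  if (is.null(op) || !cache) {
    mesh <- build_mesh(mdl$geom, mdl$ring, resolution)
    op <- forward_operator(mesh)
    if (cache) the$meshes[[op_key]] <- op
  }
  sigma <- assign_conductivity(op$mesh, mdl$geom, mdl$lesion)
  v <- as.numeric(solve_forward(op, sigma))
  if (cache) the$frames[[key]] <- v
  v
}
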
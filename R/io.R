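# File interfaces: frame-table CSV, Gmsh MSH / STL mesh export, metrics CSV
# and a self-describing JSON serialisation of trained classifiers.

#' Write / read a frame-table CSV
#'
#' Schema: header `model_id,label,snr_db,sorted,v001..v208`; voltages in
#' volts, label +1/-1, UTF-8, '.' decimal separator.
#'
#' @param data A frame dataset tibble.
#' @param path Output path.
#' @return `path` invisibly; `read_frames()` returns the dataset tibble.
#' @export
write_frames <- function(data, path) {
  cols <- c("model_id", "label", "snr_db", "sorted", grep("^v\\d+$", names(data), value = TRUE))
  readr::write_csv(data[, cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  out <- readr::read_csv(path,
    col_types = readr::cols(
      model_id = readr::col_character(),
      label = readr::col_double(),
      snr_db = readr::col_double(),
      sorted = readr::col_logical(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  dplyr::mutate(out, realisation = dplyr::row_number(),
                .after = "sorted")
}

#' Write study metrics as CSV
#'
#' @param result An `eit_study_result` or `eit_comparison` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(result, path) {
  readr::write_csv(as_tibble(result), path, progress = FALSE)
  invisible(path)
}

#' Export a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Writes nodes, tetrahedra (element type 4) and boundary triangles (type
#' 2); triangles carry their electrode number (0 = not under an electrode)
#' as the physical tag.
#'
#' @param mesh An `eit_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf(
    "%d %.12g %.12g %.12g",
    seq_len(nrow(mesh$nodes)), mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]
  ), con)
  writeLines("$EndNodes", con)
  elec_tag <- integer(nrow(mesh$boundary))
  for (l in seq_along(mesh$elec_faces)) elec_tag[mesh$elec_faces[[l]]] <- l
  n_tri <- nrow(mesh$boundary)
  n_tet <- nrow(mesh$elems)
  writeLines(c("$Elements", as.character(n_tri + n_tet)), con)
  writeLines(sprintf(
    "%d 2 2 %d 1 %d %d %d",
    seq_len(n_tri), elec_tag,
    mesh$boundary[, 1], mesh$boundary[, 2], mesh$boundary[, 3]
  ), con)
  writeLines(sprintf(
    "%d 4 2 0 1 %d %d %d %d",
    n_tri + seq_len(n_tet),
    mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3], mesh$elems[, 4]
  ), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH 2.2 ASCII mesh written by [write_mesh_msh()]
#'
#' @param path Path to the MSH file.
#' @return A list with `nodes`, `elems`, `boundary`, `elec_tag`.
#' @export
read_mesh_msh <- function(path) {
  lines <- readLines(path)
  nstart <- which(lines == "$Nodes") + 1L
  n <- as.integer(lines[nstart])
  node_rows <- do.call(rbind, strsplit(lines[nstart + seq_len(n)], " "))
  nodes <- matrix(as.numeric(node_rows[, 2:4]), ncol = 3)
  estart <- which(lines == "$Elements") + 1L
  ne <- as.integer(lines[estart])
  parts <- strsplit(lines[estart + seq_len(ne)], " ")
  types <- vapply(parts, function(p) as.integer(p[2]), 1L)
  tris <- t(vapply(parts[types == 2L], function(p) as.integer(p[6:8]), integer(3)))
  elec_tag <- vapply(parts[types == 2L], function(p) as.integer(p[4]), 1L)
  tets <- t(vapply(parts[types == 4L], function(p) as.integer(p[6:9]), integer(4)))
  list(nodes = nodes, elems = tets, boundary = tris, elec_tag = elec_tag)
}

#' Export the head or brain surface as ASCII STL
#'
#' Triangulates the requested ellipsoidal surface using the cached
#' unit-ball boundary mesh.
#'
#' @param geom An `eit_head_geometry`.
#' @param path Output path.
#' @param surface `"head"` or `"brain"`.
#' @param resolution Mesh preset controlling facet density.
#' @return `path`, invisibly.
#' @export
write_surface_stl <- function(geom, path, surface = c("head", "brain"),
                              resolution = "coarse") {
  surface <- match.arg(surface)
  um <- unit_ball_mesh(resolution)
  ax <- if (surface == "head") geom$head_semi_axes else geom$brain_semi_axes
  shift <- if (surface == "head") c(0, 0, 0) else geom$brain_centre
  nodes <- sweep(sweep(um$nodes, 2, ax, "*"), 2, shift, "+")
  tri <- um$boundary
  a <- nodes[tri[, 1], , drop = FALSE]
  u <- nodes[tri[, 2], , drop = FALSE] - a
  v <- nodes[tri[, 3], , drop = FALSE] - a
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  nl <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("solid %s", surface), con)
  fmt <- paste0(
    " facet normal %.9g %.9g %.9g\n  outer loop\n",
    "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
    "  endloop\n endfacet"
  )
  b <- nodes[tri[, 2], , drop = FALSE]
  cc <- nodes[tri[, 3], , drop = FALSE]
  writeLines(sprintf(
    fmt, nx / nl, ny / nl, nz / nl,
    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3], cc[, 1], cc[, 2], cc[, 3]
  ), con)
  writeLines(sprintf("endsolid %s", surface), con)
  invisible(path)
}

#' Serialise / restore a trained classifier as self-describing JSON
#'
#' Stores the classifier kind, hyper-parameters, calibration constants,
#' operating thresholds and the support vectors / network weights needed to
#' reproduce the decision function without the fitting libraries.
#'
#' @param clf A trained `eit_classifier`.
#' @param path Output path (JSON).
#' @return `path` invisibly; `read_classifier()` returns an
#'   `eit_classifier` whose predictions reproduce the original's.
#' @export
write_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "eit_classifier"))
  obj <- list(
    format = "eitbleed-classifier-1",
    kind = clf$kind,
    hyper = clf$hyper,
    orientation = clf$orientation,
    platt = clf$platt,
    sorted = clf$sorted,
    n_train = clf$n_train,
    auc = clf$auc,
    adjusted_tau = adjusted_threshold(clf)$tau,
    tie_rule = list(default = "-1", adjusted = "+1"),
    scale_centre = clf$scale_centre,
    scale_sd = clf$scale_sd,
    train_checksum = digest_rows(clf$train_posterior)
  )
  if (clf$kind == "nn") {
    obj$nn <- list(wts = clf$model$wts, n = clf$model$n)
  } else {
    obj$svm <- list(
      sv = unname(as.matrix(clf$model$SV)),
      coefs = as.vector(clf$model$coefs),
      rho = clf$model$rho,
      gamma = clf$model$gamma,
      labels = clf$model$labels,
      kernel = if (clf$kind == "linear_svm") "linear" else "radial"
    )
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

digest_rows <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(sprintf("%.12e", x), tmp)
  unname(tools::md5sum(tmp))
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "eitbleed-classifier-1")) {
    abort("not an eitbleed classifier file")
  }
  numeric_or_null <- function(x) {
    if (is.null(x) || length(x) == 0) NULL else as.numeric(x)
  }
  clf <- list(
    kind = obj$kind, hyper = as.list(obj$hyper), orientation = obj$orientation,
    platt = if (length(obj$platt) > 0) as.list(obj$platt) else NULL,
    sorted = obj$sorted, n_train = obj$n_train,
    auc = obj$auc, manual = TRUE, adjusted_tau = obj$adjusted_tau,
    scale_centre = numeric_or_null(obj$scale_centre),
    scale_sd = numeric_or_null(obj$scale_sd)
  )
  if (obj$kind == "nn") {
    clf$nn <- obj$nn
  } else {
    obj$svm$sv <- as.matrix(obj$svm$sv)
    clf$svm <- obj$svm
  }
  class(clf) <- c("eit_classifier_restored", "eit_classifier")
  clf
}

# Manual decision functions for restored classifiers (no fitting library
# required at prediction time).
manual_posterior <- function(clf, X) {
  if (nrow(X) == 0L) {
    return(numeric(0))
  }
  if (!is.null(clf$scale_centre)) {
    X <- sweep(sweep(X, 2, clf$scale_centre), 2, clf$scale_sd, "/")
  }
  if (clf$kind == "nn") {
    w <- as.numeric(clf$nn$wts)
    n <- as.integer(clf$nn$n) # c(inputs, hidden, outputs)
    p_in <- n[1]
    h <- n[2]
    Wh <- matrix(w[seq_len((p_in + 1) * h)], nrow = p_in + 1)
    wo <- w[(p_in + 1) * h + seq_len(h + 1)]
    H <- stats::plogis(cbind(1, X) %*% Wh)
    as.vector(stats::plogis(cbind(1, H) %*% wo))
  } else {
    sv <- clf$svm$sv
    if (clf$svm$kernel == "linear") {
      K <- X %*% t(sv)
    } else {
      d2 <- outer(rowSums(X^2), rowSums(sv^2), "+") - 2 * X %*% t(sv)
      K <- exp(-clf$svm$gamma * pmax(d2, 0))
    }
    dv <- as.vector(K %*% clf$svm$coefs) - clf$svm$rho
    platt_apply(clf$platt, clf$orientation * dv)
  }
}

#' @export
predict.eit_classifier_restored <- function(object, data,
                                            op = c("default", "adjusted", "posterior"),
                                            ...) {
  op <- match.arg(op)
  if (nrow(data) > 0L && any(data$sorted != object$sorted)) {
    abort("frame pre-processing mismatch between model and input")
  }
  p <- manual_posterior(object, frame_matrix(data))
  if (op == "posterior") {
    return(p)
  }
  q <- 1 - p
  if (op == "default") ifelse(q >= 0.5, -1, 1) else ifelse(q > object$adjusted_tau, -1, 1)
}
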
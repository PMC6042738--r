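# Parametric two-layer head geometry: an outer ellipsoidal shell of aggregate
# tissues (0.1 S/m) enclosing an ellipsoidal brain (0.3 S/m), with spherical
# haemorrhagic lesions (0.7 S/m). All lengths are SI metres internally;
# lesion volumes are millilitres at the interface.
#
# Coordinate convention: +Y anterior (north), +X right (east), +Z superior.

# Base semi-axes (m): realistic adult magnitudes for the ellipsoidal surrogate.
BASE_HEAD_SEMI_AXES <- c(0.095, 0.115, 0.120)
BASE_BRAIN_SEMI_AXES <- c(0.070, 0.085, 0.075)
BASE_BRAIN_CENTRE_OFFSET <- 0.010

SCALE_FACTORS <- c(0.95, 1.00, 1.05)
LESION_LOCATIONS <- c("north", "south", "east", "west")

#' The nine admissible per-organ anatomy variants
#'
#' Each organ (head, brain) admits nine scale variants: the base shape, and
#' the base increased or reduced by 5% along each of the X, Y, Z axes
#' individually and along all three simultaneously.
#'
#' @return A tibble with columns `variant_id`, `sx`, `sy`, `sz`.
#' @export
anatomy_variants <- function() {
  tibble(
    variant_id = c("base", "x-", "x+", "y-", "y+", "z-", "z+", "xyz-", "xyz+"),
    sx = c(1, 0.95, 1.05, 1, 1, 1, 1, 0.95, 1.05),
    sy = c(1, 1, 1, 0.95, 1.05, 1, 1, 0.95, 1.05),
    sz = c(1, 1, 1, 1, 1, 0.95, 1.05, 0.95, 1.05)
  )
}

variant_scale <- function(variant_id) {
  v <- anatomy_variants()
  i <- match(variant_id, v$variant_id)
  if (is.na(i)) abort(paste0("unknown anatomy variant '", variant_id, "'"))
  c(v$sx[i], v$sy[i], v$sz[i])
}

#' Specify a head/brain anatomy by per-axis scale factors
#'
#' @param head_scale,brain_scale Length-3 numeric vectors of per-axis scale
#'   factors, each factor one of 0.95, 1.00, 1.05; or a single `variant_id`
#'   string from [anatomy_variants()].
#' @return An object of class `eit_anatomy`.
#' @export
anatomy_spec <- function(head_scale = c(1, 1, 1), brain_scale = c(1, 1, 1)) {
  as_scale <- function(s, organ) {
    if (is.character(s) && length(s) == 1) s <- variant_scale(s)
    if (length(s) != 3 || !is.numeric(s)) {
      abort(paste0(organ, " scale must be a length-3 numeric vector"))
    }
    if (!all(vapply(s, function(x) any(abs(x - SCALE_FACTORS) < 1e-12), TRUE))) {
      abort(paste0(organ, " scale factors must each be one of 0.95, 1.00, 1.05"))
    }
    s
  }
  structure(
    list(
      head_scale = as_scale(head_scale, "head"),
      brain_scale = as_scale(brain_scale, "brain")
    ),
    class = "eit_anatomy"
  )
}

ellipsoid_value <- function(points, semi_axes, centre = c(0, 0, 0)) {
  p <- sweep(points, 2, centre)
  rowSums(sweep(p, 2, semi_axes, "/")^2)
}

# Quasi-uniform points on a unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Construct a two-layer head geometry from an anatomy specification
#'
#' Scales the base head and brain ellipsoids componentwise by the anatomy's
#' per-axis factors and verifies that the brain remains strictly inside the
#' head everywhere.
#'
#' @param anatomy An [anatomy_spec()].
#' @param min_clearance_m Minimum admissible brain-to-head clearance (m).
#' @return An object of class `eit_head_geometry` with fields
#'   `head_semi_axes`, `brain_semi_axes`, `brain_centre` (all metres) and the
#'   anatomy that produced it.
#' @export
make_head_geometry <- function(anatomy = anatomy_spec(), min_clearance_m = 1e-3) {
  stopifnot(inherits(anatomy, "eit_anatomy"))
  head_ax <- BASE_HEAD_SEMI_AXES * anatomy$head_scale
  brain_ax <- BASE_BRAIN_SEMI_AXES * anatomy$brain_scale
  centre <- c(0, 0, BASE_BRAIN_CENTRE_OFFSET)

  # Clearance: sample the brain surface, measure the radial gap to the head
  # surface (along the ray from the head centre).
  dirs <- fibonacci_sphere(2000)
  surf <- sweep(sweep(dirs, 2, brain_ax, "*"), 2, centre, "+")
  v <- ellipsoid_value(surf, head_ax) # < 1 means inside head
  rad <- sqrt(rowSums(surf^2))
  clearance <- min(rad * (1 / sqrt(pmax(v, 1e-12)) - 1))
  if (any(v >= 1) || clearance <= min_clearance_m) {
    abort(sprintf(
      "brain surface too close to head surface: minimum clearance %.2f mm (must exceed %.2f mm)",
      clearance * 1e3, min_clearance_m * 1e3
    ))
  }

  structure(
    list(
      anatomy = anatomy,
      head_semi_axes = head_ax,
      brain_semi_axes = brain_ax,
      brain_centre = centre,
      clearance = clearance
    ),
    class = "eit_head_geometry"
  )
}

#' Region membership of points in a head geometry
#'
#' @param geom An `eit_head_geometry`.
#' @param points An n-by-3 matrix of coordinates (m).
#' @param lesion Optional lesion sphere, a list with `centre` and `radius`.
#' @return A character vector: `"outer"`, `"brain"` or `"lesion"` per point.
#' @export
region_membership <- function(geom, points, lesion = NULL) {
  points <- rbind(points)
  region <- rep("outer", nrow(points))
  inside_brain <- ellipsoid_value(points, geom$brain_semi_axes, geom$brain_centre) < 1
  region[inside_brain] <- "brain"
  if (!is.null(lesion)) {
    d2 <- rowSums(sweep(points, 2, lesion$centre)^2)
    region[d2 < lesion$radius^2] <- "lesion"
  }
  region
}

#' Specify a spherical haemorrhagic lesion
#'
#' @param volume_ml Lesion volume in millilitres (> 0; the study grid uses
#'   5, 10, 20, 30 and 60 ml).
#' @param location One of `"north"` (anterior), `"south"`, `"east"`, `"west"`.
#' @param inset_mm Clearance between the lesion surface and the brain surface
#'   along the placement axis (default 2 mm).
#' @return An object of class `eit_lesion_spec`.
#' @export
lesion_spec <- function(volume_ml, location, inset_mm = 2) {
  if (!is.numeric(volume_ml) || volume_ml <= 0) abort("lesion volume must be positive")
  location <- match.arg(location, LESION_LOCATIONS)
  structure(
    list(volume_ml = volume_ml, location = location, inset_mm = inset_mm),
    class = "eit_lesion_spec"
  )
}

#' Radius of a sphere of given volume
#'
#' @param volume_ml Volume in millilitres.
#' @return Radius in metres, `(3V / 4 pi)^(1/3)` with V in cubic metres.
#' @export
lesion_radius <- function(volume_ml) {
  if (!is.numeric(volume_ml) || any(volume_ml <= 0)) {
    abort("lesion volume must be positive")
  }
  (3 * volume_ml * 1e-6 / (4 * pi))^(1 / 3)
}

#' Specify the 16-electrode ring
#'
#' @param height_offset_mm Vertical offset of the ring plane from the nominal
#'   plane through the brain centre: one of -2, 0, +2 mm.
#' @param electrode_radius_mm Contact patch radius (mm).
#' @param contact_impedance Contact impedance (Ohm m^2; the default 0.05
#'   corresponds to a ~640 Ohm contact for a 5 mm patch, typical of gelled
#'   EEG-style electrodes at 50 kHz).
#' @param n_electrodes Number of electrodes (16).
#' @param current_a Injected current amplitude (A).
#' @return An object of class `eit_ring_spec`.
#' @export
electrode_ring_spec <- function(height_offset_mm = 0, electrode_radius_mm = 5,
                                contact_impedance = 0.05, n_electrodes = 16L,
                                current_a = 1e-3) {
  structure(
    list(
      n_electrodes = as.integer(n_electrodes),
      height_offset_mm = height_offset_mm,
      electrode_radius_mm = electrode_radius_mm,
      contact_impedance = contact_impedance,
      current_a = current_a
    ),
    class = "eit_ring_spec"
  )
}

ring_plane_z <- function(geom, ring = NULL) {
  off <- if (is.null(ring)) 0 else ring$height_offset_mm * 1e-3
  geom$brain_centre[3] + off
}

cardinal_axis <- function(location) {
  switch(location,
    north = c(0, 1, 0),
    south = c(0, -1, 0),
    east = c(1, 0, 0),
    west = c(-1, 0, 0)
  )
}

#' Place a lesion sphere inside the brain
#'
#' The sphere centre lies on the cardinal axis in the nominal ring plane,
#' positioned so that the sphere surface sits `inset_mm` inside the brain
#' surface along that axis.
#'
#' @param geom An `eit_head_geometry`.
#' @param lesion An [lesion_spec()].
#' @param ring Optional ring spec (the lesion plane is the *nominal* ring
#'   plane through the brain centre, unaffected by ring height offsets).
#' @return A list with `centre` (m), `radius` (m), `volume_ml`, `location`.
#' @export
place_lesion <- function(geom, lesion, ring = NULL) {
  stopifnot(inherits(geom, "eit_head_geometry"), inherits(lesion, "eit_lesion_spec"))
  r <- lesion_radius(lesion$volume_ml)
  inset <- lesion$inset_mm * 1e-3
  z0 <- geom$brain_centre[3] # nominal ring plane
  axis <- cardinal_axis(lesion$location)

  # Brain boundary distance from the brain centre along the cardinal axis in
  # the plane z = z0 (which passes through the brain centre, so the in-plane
  # section has the full in-plane semi-axes).
  semi <- if (lesion$location %in% c("east", "west")) geom$brain_semi_axes[1] else geom$brain_semi_axes[2]
  dist_centre <- semi - inset - r
  if (dist_centre < r) {
    abort(sprintf(
      "lesion does not fit: %g ml sphere (r = %.1f mm) with %.1f mm inset would cross the brain centreline (available distance %.1f mm)",
      lesion$volume_ml, r * 1e3, lesion$inset_mm, (semi - inset) * 1e3
    ))
  }
  centre <- c(0, 0, z0) + axis * dist_centre

  # Whole-sphere containment against the curved brain surface.
  pts <- sweep(fibonacci_sphere(500) * r, 2, centre, "+")
  vals <- ellipsoid_value(pts, geom$brain_semi_axes, geom$brain_centre)
  if (any(vals >= 1)) {
    worst <- max(vals)
    abort(sprintf(
      "lesion sphere protrudes through the brain surface (worst membership value %.3f > 1); reduce volume or inset",
      worst
    ))
  }
  list(
    centre = centre, radius = r,
    volume_ml = lesion$volume_ml, location = lesion$location
  )
}

#' Electrode centre positions on the head surface
#'
#' Sixteen points equally spaced in arc length along the closed curve where
#' the ring plane cuts the head surface. Numbering follows convention:
#' electrodes 1 and 16 flank the north (anterior, +Y) position, with numbers
#' increasing eastward, so the layout is symmetric across the sagittal
#' (X = 0) plane.
#'
#' @param geom An `eit_head_geometry`.
#' @param ring An [electrode_ring_spec()].
#' @return A 16-by-3 matrix of coordinates (m), rows ordered by electrode.
#' @export
electrode_positions <- function(geom, ring = electrode_ring_spec()) {
  z <- ring_plane_z(geom, ring)
  c2 <- 1 - (z / geom$head_semi_axes[3])^2
  if (c2 <= 0) abort("ring plane does not intersect the head surface")
  a <- geom$head_semi_axes[1] * sqrt(c2)
  b <- geom$head_semi_axes[2] * sqrt(c2)

  # Arc-length parametrisation of the ellipse x = a sin t, y = b cos t
  # (t = 0 at north, increasing towards east/+X).
  tt <- seq(0, 2 * pi, length.out = 4097)
  xs <- a * sin(tt)
  ys <- b * cos(tt)
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  s <- c(0, cumsum(seg))
  per <- s[length(s)]
  n <- ring$n_electrodes
  # Electrode k is centred at arc fraction (k - 1/2)/n east of north, so
  # electrodes 1 and 16 straddle the north point.
  targets <- (seq_len(n) - 0.5) / n * per
  tk <- approx(s, tt, xout = targets)$y
  cbind(a * sin(tk), b * cos(tk), rep(z, n))
}

#' Enumerate the model grid
#'
#' The normal-model grid is 9 head variants x 9 brain variants x ring
#' heights; each normal model combines with every lesion volume in `volumes_ml`
#' at each of the four cardinal locations to form the lesion-model grid
#' (9 x 9 x 3 = 243 normals and 243 x 2 x 4 = 1944 lesion models for the
#' default three heights and 30/60 ml volumes).
#'
#' @param heights Integer: number of ring heights (1 uses offset 0; 3 uses
#'   -2, 0, +2 mm).
#' @param with_lesions If `TRUE`, return lesion-model descriptors.
#' @param volumes_ml Lesion volumes used for the lesion grid.
#' @param head_variants,brain_variants Subsets of [anatomy_variants()]
#'   `variant_id`s (defaults: all nine).
#' @return A tibble of model descriptors with columns `model_id`,
#'   `head_variant`, `brain_variant`, `height_offset_mm`, `lesion_volume_ml`,
#'   `lesion_location`, `label` (+1 bleed, -1 normal), in deterministic order.
#' @export
enumerate_models <- function(heights = 3, with_lesions = FALSE,
                             volumes_ml = c(30, 60),
                             head_variants = anatomy_variants()$variant_id,
                             brain_variants = anatomy_variants()$variant_id) {
  offsets <- switch(as.character(heights),
    "1" = 0,
    "2" = c(-2, 0),
    "3" = c(-2, 0, 2),
    abort("heights must be 1, 2 or 3")
  )
  normals <- tidyr::expand_grid(
    head_variant = head_variants,
    brain_variant = brain_variants,
    height_offset_mm = offsets
  )
  if (!with_lesions) {
    out <- normals |>
      dplyr::mutate(
        lesion_volume_ml = NA_real_, lesion_location = NA_character_,
        label = -1
      )
  } else {
    out <- tidyr::expand_grid(
      normals,
      lesion_volume_ml = volumes_ml,
      lesion_location = LESION_LOCATIONS
    ) |>
      dplyr::mutate(label = 1)
  }
  out |>
    dplyr::mutate(
      model_id = paste0(
        "h=", .data$head_variant, ";b=", .data$brain_variant,
        ";z=", .data$height_offset_mm,
        ifelse(.data$label > 0,
          paste0(";les=", .data$lesion_volume_ml, "ml@", .data$lesion_location),
          ";normal"
        )
      ),
      .before = 1
    )
}

#' Materialise a model descriptor row into geometry objects
#'
#' @param descriptor A single row of [enumerate_models()].
#' @param inset_mm Lesion inset passed to [lesion_spec()].
#' @return A list with `geom`, `ring`, and `lesion` (`NULL` for normals).
#' @export
build_model <- function(descriptor, inset_mm = 2) {
  stopifnot(nrow(descriptor) == 1)
  geom <- make_head_geometry(anatomy_spec(
    head_scale = descriptor$head_variant,
    brain_scale = descriptor$brain_variant
  ))
  ring <- electrode_ring_spec(height_offset_mm = descriptor$height_offset_mm)
  lesion <- NULL
  if (!is.na(descriptor$lesion_volume_ml)) {
    lesion <- place_lesion(
      geom,
      lesion_spec(descriptor$lesion_volume_ml, descriptor$lesion_location, inset_mm),
      ring
    )
  }
  list(geom = geom, ring = ring, lesion = lesion)
}
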
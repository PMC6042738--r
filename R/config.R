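# Plumbing: deterministic named seed streams, validated YAML study
# configuration, fixture meshes for fast tests, and run manifests.

#' Derive a named child seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' streams (FNV-1a hash of the stream name folded with the master seed), so
#' studies and stages never share or re-use a stream.
#'
#' @param master Integer master seed.
#' @param name Stream name (e.g. `"noise-train-60"`).
#' @return A positive integer seed below 2^31.
#' @export
seed_stream <- function(master, name) {
  h <- 2166136261
  for (b in utf8ToInt(name)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  as.integer((h + as.numeric(master)) %% (2^31 - 1)) + 1L
}

STUDY_NAMES <- c(
  "noise", "location", "size_down", "size_up", "electrode",
  "anatomy", "overall", "comparison"
)

#' Construct a validated study configuration
#'
#' @param study One of `"noise"`, `"location"`, `"size_down"`, `"size_up"`,
#'   `"electrode"`, `"anatomy"`, `"overall"`, `"comparison"`.
#' @param snr_db SNR grid in dB.
#' @param scale Frame-budget scale factor in (0, 1].
#' @param seed Master seed.
#' @param resolution Mesh preset.
#' @param sorted Frame variants to run (any of `FALSE`, `TRUE`).
#' @param budget Hyper-parameter search budget.
#' @return An object of class `eit_study_config`.
#' @export
study_config <- function(study, snr_db = c(80, 60, 40, 20), scale = 1.0,
                         seed = 0L, resolution = "coarse",
                         sorted = c(FALSE, TRUE), budget = 30L) {
  study <- match.arg(study, STUDY_NAMES)
  if (!is.numeric(scale) || scale <= 0 || scale > 1) {
    abort("scale must lie in (0, 1]")
  }
  if (!all(snr_db > 0)) abort("snr_db values must be positive")
  structure(
    list(
      study = study, snr_db = snr_db, scale = scale, seed = as.integer(seed),
      resolution = resolution, sorted = sorted, budget = as.integer(budget)
    ),
    class = "eit_study_config"
  )
}

#' Load a study configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [study_config()]
#' defaults.
#'
#' @param path Path to a YAML file with keys drawn from the
#'   [study_config()] arguments.
#' @return An `eit_study_config`.
#' @export
load_study_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(study_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$study)) abort("config must name a study")
  do.call(study_config, raw)
}

#' Save a study configuration as YAML
#'
#' @param config An `eit_study_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_study_config <- function(config, path) {
  stopifnot(inherits(config, "eit_study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a study configuration
#'
#' MD5 of the canonical YAML serialisation; identical configurations hash
#' identically across sessions.
#'
#' @param config An `eit_study_config`.
#' @return A hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  save_study_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Build the small test fixture: coarse base-model mesh and sub-grid
#'
#' Returns the base-geometry coarse mesh (cached for the session) together
#' with the 9-model normal sub-grid descriptors (head x brain in
#' {-5% XYZ, base, +5% XYZ} at ring height 0), used to keep test runtimes
#' small.
#'
#' @param resolution Mesh preset (default `"coarse"`).
#' @return A list with `geom`, `ring`, `mesh`, `descriptors`.
#' @export
make_fixture <- function(resolution = "coarse") {
  geom <- make_head_geometry(anatomy_spec())
  ring <- electrode_ring_spec()
  mesh <- build_mesh(geom, ring, resolution)
  descriptors <- enumerate_models(
    heights = 1,
    head_variants = c("xyz-", "base", "xyz+"),
    brain_variants = c("xyz-", "base", "xyz+")
  )
  list(geom = geom, ring = ring, mesh = mesh, descriptors = descriptors)
}

#' Manifest of emitted artifact files
#'
#' @param config The `eit_study_config` that produced the artifacts.
#' @param files Character vector of file paths.
#' @return A tibble with package version, config hash, master seed and an
#'   MD5 checksum per file.
#' @export
run_manifest <- function(config, files) {
  tibble(
    package_version = as.character(utils::packageVersion("eitbleed")),
    config_hash = config_hash(config),
    seed = config$seed,
    file = files,
    md5 = unname(tools::md5sum(files))
  )
}
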
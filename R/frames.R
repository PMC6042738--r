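# Labelled frame datasets: SNR-controlled measurement noise, the sorted-frame
# pre-processing step, SNR estimation from repeated frames, and the
# maximal-difference-channel analysis.
#
# Datasets are tibbles with one row per frame: metadata columns
# (model_id, label, snr_db, sorted, realisation) followed by the 208 channel
# columns v001..v208 (volts).

channel_cols <- function(n = 208) sprintf("v%03d", seq_len(n))

#' Extract the channel matrix from a frame dataset
#'
#' @param data A frame dataset tibble.
#' @return A numeric matrix, rows = frames, columns = channels.
#' @export
frame_matrix <- function(data) {
  cols <- grep("^v\\d+$", names(data), value = TRUE)
  if (length(cols) == 0L) abort("no channel columns (v001, v002, ...) found")
  as.matrix(data[, cols])
}

#' Add SNR-controlled Gaussian measurement noise to a frame
#'
#' Noise is independent Gaussian per channel with standard deviation
#' proportional to that channel's noiseless magnitude,
#' `sd_c = |v_c| * 10^(-snr_db/20)`, so both the per-channel and the whole
#' frame expected signal-to-noise power ratios equal `snr_db`. The noisy
#' frame is re-clamped to magnitudes by absolute value. `snr_db = Inf`
#' returns the frame unchanged.
#'
#' @param frame Numeric vector of channel voltage magnitudes (V).
#' @param snr_db Signal-to-noise ratio in dB (finite or `Inf`).
#' @return Numeric vector of the same length.
#' @export
add_noise <- function(frame, snr_db) {
  v <- as.numeric(frame)
  if (all(v == 0)) abort("SNR is undefined for an all-zero frame")
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db)) {
    abort("snr_db must be a single finite number or Inf")
  }
  if (is.infinite(snr_db)) {
    return(v)
  }
  abs(v + rnorm(length(v), sd = abs(v) * 10^(-snr_db / 20)))
}

#' Sort each frame's channel values ascending
#'
#' The sorted-frame pre-processing step discards channel identity to gain
#' invariance to lesion location. Labels and metadata are preserved; the
#' `sorted` flag is set.
#'
#' @param data A frame dataset tibble (or a bare numeric frame vector).
#' @return The dataset with each row's channel values rearranged ascending.
#' @export
sort_frames <- function(data) {
  if (is.numeric(data) && is.null(dim(data))) {
    return(sort(data))
  }
  m <- frame_matrix(data)
  cols <- grep("^v\\d+$", names(data), value = TRUE)
  sorted <- t(apply(m, 1, sort))
  data[, cols] <- as_tibble(stats::setNames(as.data.frame(sorted), cols))
  if ("sorted" %in% names(data)) data$sorted <- TRUE
  data
}

#' Estimate the SNR of a set of repeated frames
#'
#' For each measurement channel, the ratio of the mean to the standard
#' deviation of its values over all frames is converted to dB
#' (`20 log10(|mean| / sd)`); the estimate is the average over channels.
#' Channels with zero standard deviation are excluded and reported via the
#' `"excluded_channels"` attribute.
#'
#' @param frames A frame dataset tibble or a numeric matrix
#'   (rows = frames).
#' @return Estimated SNR in dB.
#' @export
estimate_snr <- function(frames) {
  m <- if (is.matrix(frames)) frames else frame_matrix(frames)
  if (nrow(m) < 2L) abort("at least 2 frames are required to estimate SNR")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  ok <- s > 0
  if (!any(ok)) abort("all channels are constant across frames; SNR undefined")
  est <- mean(20 * log10(abs(mu[ok]) / s[ok]))
  structure(est, excluded_channels = which(!ok))
}

#' Channel with the maximal mean difference between two datasets
#'
#' @param normal,lesion Frame datasets (or matrices) with equal channel
#'   counts.
#' @param pattern Optional stimulation pattern; if supplied, the winning
#'   channel's electrode quadruple is included in the result.
#' @return A one-row tibble with `channel`, `mean_difference` (V; mean normal
#'   minus mean lesion) and, when `pattern` is given, the channel's
#'   electrodes. Ties break to the lowest channel index.
#' @export
max_diff_channel <- function(normal, lesion, pattern = NULL) {
  mn <- if (is.matrix(normal)) normal else frame_matrix(normal)
  ml <- if (is.matrix(lesion)) lesion else frame_matrix(lesion)
  if (ncol(mn) != ncol(ml)) abort("channel counts differ between datasets")
  if (nrow(mn) == 0L || nrow(ml) == 0L) abort("both datasets must be non-empty")
  d <- colMeans(mn) - colMeans(ml)
  ch <- which.max(abs(d)) # which.max takes the first (lowest) index on ties
  out <- tibble(channel = as.integer(ch), mean_difference = d[ch])
  if (!is.null(pattern)) {
    out <- dplyr::bind_cols(out, pattern[ch, c("inj_pos", "inj_neg", "meas_pos", "meas_neg")])
  }
  out
}

#' Generate a labelled frame dataset from model descriptors
#'
#' One (cached) forward solve per distinct model, then the requested number
#' of independent noise realisations per model. Rows are shuffled
#' deterministically under the seed.
#'
#' @param models A tibble of model descriptors ([enumerate_models()] rows).
#' @param frames_per_model Integer vector (recycled) of realisation counts
#'   per model row.
#' @param snr_db SNR of the added noise (dB, or `Inf` for noiseless).
#' @param sorted Sort each frame's values ascending.
#' @param seed Integer seed; the dataset is bit-reproducible given
#'   (models, counts, snr_db, sorted, seed).
#' @param resolution Mesh preset for the forward solves.
#' @return A frame dataset tibble.
#' @export
make_dataset <- function(models, frames_per_model, snr_db = Inf, sorted = FALSE,
                         seed = 1L, resolution = "coarse") {
  stopifnot(is.data.frame(models), nrow(models) >= 1L)
  counts <- as.integer(rep_len(frames_per_model, nrow(models)))
  if (any(counts < 0L)) abort("frames_per_model must be non-negative")
  cols <- channel_cols()
  parts <- vector("list", nrow(models))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (q in seq_len(nrow(models))) {
    if (counts[q] == 0L) next
    v <- simulate_frame(models[q, ], resolution = resolution)
    noisy <- t(vapply(seq_len(counts[q]), function(r) add_noise(v, snr_db),
                      numeric(length(v))))
    part <- tibble(
      model_id = models$model_id[q],
      label = models$label[q],
      snr_db = snr_db,
      sorted = FALSE,
      realisation = seq_len(counts[q])
    )
    part[, cols] <- as_tibble(stats::setNames(as.data.frame(noisy), cols))
    parts[[q]] <- part
  }
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0L) {
    out <- tibble(
      model_id = character(), label = numeric(), snr_db = numeric(),
      sorted = logical(), realisation = integer()
    )
    out[, cols] <- as_tibble(stats::setNames(
      as.data.frame(matrix(numeric(0), 0, length(cols))), cols
    ))
    return(out)
  }
  out <- out[sample.int(nrow(out)), ]
  if (sorted) out <- sort_frames(out)
  out
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
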
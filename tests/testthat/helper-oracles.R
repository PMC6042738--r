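# Shared fixtures and independent oracles.

base_descriptor <- function() {
  enumerate_models(heights = 1)[
    enumerate_models(heights = 1)$model_id == "h=base;b=base;z=0;normal",
  ]
}

base_frame <- function() {
  # Cached by the package across tests in this session.
  simulate_frame(base_descriptor(), resolution = "coarse")
}

# Brute-force skip-pattern oracle: enumerate every (injection, measurement)
# combination and apply the exclusion rule directly.
brute_force_pattern <- function(n, skip) {
  wrap <- function(x) ((x - 1) %% n) + 1
  out <- NULL
  for (i in seq_len(n)) {
    inj <- c(i, wrap(i + skip + 1))
    for (m in seq_len(n)) {
      meas <- c(m, wrap(m + skip + 1))
      if (length(intersect(inj, meas)) == 0) out <- rbind(out, c(inj, meas))
    }
  }
  out
}

# Mann-Whitney U formulation of the AUC (midrank tie handling).
mw_auc <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels < 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Small linearly separable synthetic frame dataset (blobs in 208-d).
blob_dataset <- function(n_per_class = 15, gap = 5, seed = 7, sorted = FALSE) {
  set.seed(seed)
  p <- 208
  x_pos <- matrix(rnorm(n_per_class * p), n_per_class) + gap / sqrt(p)
  x_neg <- matrix(rnorm(n_per_class * p), n_per_class) - gap / sqrt(p)
  m <- rbind(x_pos, x_neg)
  cols <- sprintf("v%03d", seq_len(p))
  out <- tibble::tibble(
    model_id = rep(c("blob+", "blob-"), each = n_per_class),
    label = rep(c(1, -1), each = n_per_class),
    snr_db = Inf, sorted = sorted,
    realisation = seq_len(2 * n_per_class)
  )
  out[, cols] <- as.data.frame(m)
  out
}

# Apply an operating point directly to posteriors (independent of predict()).
classify_at <- function(p_pos, tau, tie_bleed) {
  q <- 1 - p_pos
  if (tie_bleed) ifelse(q > tau, -1, 1) else ifelse(q >= tau, -1, 1)
}
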
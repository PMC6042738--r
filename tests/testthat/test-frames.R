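test_that("infinite SNR returns the frame unchanged; zero frames are rejected", {
  v <- base_frame()
  expect_identical(add_noise(v, Inf), v)
  expect_error(add_noise(rep(0, 208), 60), "all-zero")
  expect_error(add_noise(v, NA_real_), "snr_db")
})

test_that("realised frame-level SNR matches the nominal level", {
  v <- base_frame()
  set.seed(101)
  realised <- replicate(1000, {
    noisy <- add_noise(v, 60)
    20 * log10(sqrt(mean(v^2)) / sqrt(mean((noisy - v)^2)))
  })
  # per-channel proportional scaling gives the nominal frame power ratio in
  # expectation (small upward bias ~0.08 dB from the log of a ratio)
  expect_equal(mean(realised), 60, tolerance = 0.2)
})

test_that("noise realisations from distinct draws are independent", {
  v <- base_frame()
  set.seed(5)
  n1 <- add_noise(v, 40) - v
  n2 <- add_noise(v, 40) - v
  expect_lt(abs(cor(n1, n2)), 0.2)
})

test_that("sorting rearranges values ascending and preserves everything else", {
  d <- blob_dataset(4)
  s <- sort_frames(d)
  m <- frame_matrix(d)
  ms <- frame_matrix(s)
  expect_true(all(apply(ms, 1, function(r) !is.unsorted(r))))
  for (i in seq_len(nrow(m))) expect_equal(unname(sort(m[i, ])), unname(ms[i, ]))
  expect_identical(s$label, d$label)
  expect_identical(s$model_id, d$model_id)
  expect_true(all(s$sorted))
  # idempotence and permutation invariance
  expect_equal(frame_matrix(sort_frames(s)), ms)
  perm <- d
  cols <- sprintf("v%03d", 1:208)
  perm[, cols] <- d[, sample(cols)]
  expect_equal(frame_matrix(sort_frames(perm)), ms)
  # plain numeric vectors sort too
  expect_equal(sort_frames(c(3, 1, 2) * 1e-3), c(1, 2, 3) * 1e-3)
})

test_that("estimate_snr implements the per-channel mean/sd rule in dB", {
  # two frames engineered to an exact mean 1, sd 0.01 on every channel
  d <- 0.01 / sqrt(2)
  m <- rbind(rep(1 - d, 208), rep(1 + d, 208))
  expect_equal(as.numeric(estimate_snr(m)), 40, tolerance = 1e-9)

  # aggregation is the mean over channels: 20 dB and 60 dB average to 40
  m2 <- cbind(
    c(1 - 0.1 / sqrt(2), 1 + 0.1 / sqrt(2)), # 20 dB
    c(1 - 0.001 / sqrt(2), 1 + 0.001 / sqrt(2)) # 60 dB
  )
  expect_equal(as.numeric(estimate_snr(m2)), 40, tolerance = 1e-9)

  expect_error(estimate_snr(m[1, , drop = FALSE]), "at least 2")
  expect_error(estimate_snr(rbind(m[1, ], m[1, ])), "constant")

  # constant channels are excluded and reported
  m3 <- cbind(m, c(2, 2))
  est <- estimate_snr(m3)
  expect_equal(attr(est, "excluded_channels"), 209)
})

test_that("estimate_snr recovers the injected SNR within 1 dB", {
  v <- base_frame()
  for (X in c(20, 40, 60, 80)) {
    set.seed(X)
    mat <- t(vapply(1:500, function(i) add_noise(v, X), numeric(208)))
    expect_equal(as.numeric(estimate_snr(mat)), X, tolerance = 1)
  }
})

test_that("max_diff_channel picks the largest mean difference with low-index ties", {
  nrm <- matrix(1, 4, 2)
  les <- cbind(rep(1, 4), rep(0.5, 4))
  res <- max_diff_channel(nrm, les)
  expect_equal(res$channel, 2L)
  expect_equal(res$mean_difference, 0.5)

  tie <- max_diff_channel(nrm, nrm)
  expect_equal(tie$channel, 1L)
  expect_equal(tie$mean_difference, 0)

  expect_error(max_diff_channel(nrm, les[, 1, drop = FALSE]), "channel counts")
  expect_error(max_diff_channel(nrm[0, , drop = FALSE], les), "non-empty")
})

test_that("the maximal-difference channel for a north lesion adjoins north electrodes", {
  models <- dplyr::bind_rows(
    base_descriptor(),
    enumerate_models(1, with_lesions = TRUE)[
      enumerate_models(1, with_lesions = TRUE)$model_id ==
        "h=base;b=base;z=0;les=60ml@north",
    ]
  )
  d <- make_dataset(models, c(30, 30), snr_db = 80, seed = 3)
  pat <- build_stim_pattern(16, 2)
  res <- max_diff_channel(
    d[d$label < 0, ], d[d$label > 0, ],
    pattern = pat
  )
  expect_true(any(unlist(res[, c("inj_pos", "inj_neg", "meas_pos", "meas_neg")]) %in%
    c(1, 2, 15, 16)))
})

test_that("make_dataset respects budgets, labels, shuffling and determinism", {
  models <- dplyr::bind_rows(
    base_descriptor(),
    enumerate_models(1, with_lesions = TRUE)[
      enumerate_models(1, with_lesions = TRUE)$model_id %in%
        c("h=base;b=base;z=0;les=30ml@north", "h=base;b=base;z=0;les=60ml@north"),
    ]
  )
  d <- make_dataset(models, c(20, 10, 10), snr_db = 60, seed = 9)
  expect_equal(nrow(d), 40)
  expect_equal(sum(d$label < 0), 20)
  expect_equal(sum(d$label > 0), 20)
  expect_true("realisation" %in% names(d))

  d2 <- make_dataset(models, c(20, 10, 10), snr_db = 60, seed = 9)
  expect_identical(d, d2)
  d3 <- make_dataset(models, c(20, 10, 10), snr_db = 60, seed = 10)
  expect_false(identical(d, d3))

  empty <- make_dataset(models, 0, snr_db = 60, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(sprintf("v%03d", 1:208) %in% names(empty)))
})
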
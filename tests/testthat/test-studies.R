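# Scaled-down study smoke runs; forward solutions are cached across tests,
# so these mostly exercise dataset assembly, training and bookkeeping.

tiny_budget <- 5

test_that("the noise study reports every configured cell with valid rates", {
  res <- run_noise_study(
    snr_db = 60, n_train_normal = 40, n_train_per_lesion = 20,
    n_test_normal = 20, n_test_per_lesion = 10,
    seed = 2, budget = tiny_budget
  )
  expect_s3_class(res, "eit_study_result")
  expect_equal(nrow(res), 4) # 2 frame types x 2 operating points
  expect_true(all(res$sensitivity >= 0 & res$sensitivity <= 1))
  expect_true(all(res$specificity >= 0 & res$specificity <= 1))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_setequal(unique(res$op), c("default", "adjusted"))

  md <- attr(res, "max_diff")
  expect_equal(nrow(md), 2) # one per lesion volume
  expect_true(all(md$channel %in% 1:208))

  # adjusted-vs-default monotonicity in every cell pair
  wide <- tidyr::pivot_wider(res[, c("frames", "op", "sensitivity", "specificity")],
    names_from = "op", values_from = c("sensitivity", "specificity")
  )
  expect_true(all(wide$sensitivity_adjusted >= wide$sensitivity_default))
  expect_true(all(wide$specificity_adjusted <= wide$specificity_default))
})

test_that("studies are bit-reproducible from (config, seed)", {
  args <- list(
    snr_db = 60, n_train_normal = 30, n_train_per_lesion = 15,
    n_test_normal = 10, n_test_per_lesion = 5, seed = 11, budget = tiny_budget,
    sorted = FALSE
  )
  r1 <- do.call(run_noise_study, args)
  r2 <- do.call(run_noise_study, args)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- do.call(run_noise_study, modifyList(args, list(seed = 12)))
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("the location study tests only unseen lesion locations", {
  res <- run_location_study(
    snr_db = 60, n_train_normal = 40, n_train_per_lesion = 20,
    n_test_normal = 24, n_test_per_lesion = 4,
    seed = 3, budget = tiny_budget, sorted = TRUE
  )
  expect_equal(nrow(res), 2)
  expect_true(all(res$tp + res$fn == 24)) # 6 off-north models x 4 frames
  expect_true(all(res$tn + res$fp == 24))
})

test_that("the size study trains once per frame type and tests per volume", {
  res <- run_size_study(
    direction = "down", test_volumes_ml = c(30, 10),
    n_train_normal = 40, n_train_per_lesion = 10,
    n_test_normal = 12, n_test_per_lesion = 3,
    seed = 4, budget = tiny_budget, sorted = FALSE
  )
  expect_equal(nrow(res), 4) # 2 volumes x 1 frame type x 2 ops
  expect_setequal(unique(res$test_volume_ml), c(30, 10))
  expect_equal(unique(res$train_volume_ml), 60)
  expect_length(unique(res$auc), 1) # one classifier per frame type
})

test_that("the electrode study control (no shift) classifies perfectly at 60 dB", {
  res <- run_electrode_study(
    test_offsets_mm = 0,
    n_train_normal = 40, n_train_per_lesion = 5,
    n_test_normal = 20, n_test_per_lesion = 2,
    seed = 5, budget = tiny_budget, sorted = FALSE
  )
  ctrl <- res[res$op == "default", ]
  expect_equal(ctrl$sensitivity, 1)
  expect_equal(ctrl$specificity, 1)
})

test_that("the anatomy study reports the volume-ratio diagnostic", {
  anat <- tibble::tibble(
    head_variant = c("xyz+", "xyz-"),
    brain_variant = c("xyz-", "xyz+")
  )
  res <- run_anatomy_study(
    test_anatomies = anat,
    n_train_normal = 40, n_train_per_lesion = 5,
    n_test_normal_frames = 8, n_test_lesion_frames = 1,
    seed = 6, budget = tiny_budget, sorted = FALSE
  )
  expect_equal(nrow(res), 2)
  diag <- attr(res, "anatomy_diagnostic")
  expect_true(all(c("ratio_label_correlation", "frac_normal_when_ratio_high") %in%
    names(diag)))
})

mini_grid <- function() {
  sub_h <- "base"
  sub_b <- c("base", "xyz+")
  dplyr::bind_rows(
    enumerate_models(1, head_variants = sub_h, brain_variants = sub_b),
    enumerate_models(1,
      with_lesions = TRUE,
      head_variants = sub_h, brain_variants = sub_b
    )
  )
}

test_that("the pooled overall study keeps classes and per-model budgets balanced", {
  grid <- mini_grid() # 2 normal + 16 lesion models
  res <- run_overall_study(
    snr_db = 60, grid = grid,
    n_train_per_normal = 16, n_train_per_lesion = 2,
    n_test_per_normal = 8, n_test_per_lesion = 1,
    seed = 7, budget = tiny_budget, sorted = FALSE
  )
  expect_true(all(res$tp + res$fn == 16)) # 16 lesion models x 1 frame
  expect_true(all(res$tn + res$fp == 16))

  # balance invariants of the generated sets
  train <- eitbleed:::pooled_dataset(60, 16, 2,
    sorted = FALSE,
    seed = seed_stream(7, "overall-train-60"), resolution = "coarse", grid = grid
  )
  expect_equal(sum(train$label > 0), sum(train$label < 0))
  counts <- table(train$model_id[train$label > 0])
  expect_true(all(counts == counts[1]))
})

test_that("the classifier comparison runs the ten-fold 90/10 scheme per kind", {
  res <- run_classifier_comparison(
    snr_db = 60, kinds = "linear_svm", grid = mini_grid(),
    n_per_normal = 24, n_per_lesion = 3,
    seed = 8, budget = tiny_budget
  )
  expect_s3_class(res, "eit_comparison")
  expect_equal(nrow(res), 1)
  folds <- attr(res, "folds")
  expect_equal(nrow(folds), 10)
  expect_true(all(folds$tp + folds$fp + folds$tn + folds$fn %in% c(9, 10)))
  expect_true(res$sensitivity_mean >= 0 && res$sensitivity_mean <= 1)

  res2 <- run_classifier_comparison(
    snr_db = 60, kinds = "linear_svm", grid = mini_grid(),
    n_per_normal = 24, n_per_lesion = 3,
    seed = 8, budget = tiny_budget
  )
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("study results plot without error", {
  res <- run_noise_study(
    snr_db = 60, n_train_normal = 30, n_train_per_lesion = 15,
    n_test_normal = 10, n_test_per_lesion = 5, seed = 2, budget = tiny_budget
  )
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  d <- blob_dataset(5)
  clf <- train_classifier(d, classifier_spec(budget = 5), seed = 1)
  expect_s3_class(autoplot(clf), "ggplot")
  expect_s3_class(plot_frame(base_frame()), "ggplot")
})
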
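# Seeded experiment runners reproducing the numerical studies: effect of
# noise, lesion location, lesion size, electrode positioning and anatomy,
# the pooled overall study, and the three-classifier comparison. Each runner
# is bit-reproducible from (arguments, seed); all randomness flows through
# named seed streams derived from the master seed.

make_descriptors <- function(head = "base", brain = "base", height = 0,
                             volume_ml = NA, location = NA) {
  grid <- tidyr::expand_grid(
    head_variant = head, brain_variant = brain, height_offset_mm = height,
    lesion_volume_ml = volume_ml, lesion_location = location
  )
  grid |>
    dplyr::mutate(
      label = ifelse(is.na(.data$lesion_volume_ml), -1, 1),
      model_id = paste0(
        "h=", .data$head_variant, ";b=", .data$brain_variant,
        ";z=", .data$height_offset_mm,
        ifelse(.data$label > 0,
          paste0(";les=", .data$lesion_volume_ml, "ml@", .data$lesion_location),
          ";normal"
        )
      )
    ) |>
    dplyr::relocate("model_id")
}

study_result <- function(rows, study, config = list()) {
  out <- dplyr::bind_rows(rows)
  attr(out, "study") <- study
  attr(out, "config") <- config
  class(out) <- c("eit_study_result", class(out))
  out
}

#' @export
print.eit_study_result <- function(x, ...) {
  cat(sprintf("<eit_study_result> study '%s', %d cells\n", attr(x, "study"), nrow(x)))
  NextMethod()
}

# Train one linear SVM on `train`, evaluate on `test` at the requested
# operating points; returns one metrics row per operating point.
train_eval_cells <- function(train, test, spec, seed,
                             ops = c("default", "adjusted"), extra = list()) {
  clf <- train_classifier(train, spec, seed = seed)
  rows <- lapply(ops, function(op) {
    pred <- predict(clf, test, op = op)
    dplyr::bind_cols(
      as_tibble(extra),
      tibble(
        frames = if (clf$sorted) "sorted" else "unaltered",
        op = op, auc = clf$auc
      ),
      evaluate_predictions(test$label, pred)
    )
  })
  list(clf = clf, rows = dplyr::bind_rows(rows))
}

# Shared recipe: train on the base model plus 30/60 ml north lesions.
north_train_models <- function() {
  dplyr::bind_rows(
    make_descriptors(),
    make_descriptors(volume_ml = 30, location = "north"),
    make_descriptors(volume_ml = 60, location = "north")
  )
}

#' Study: effect of measurement noise
#'
#' Base model plus 30/60 ml north lesions; a linear SVM per (SNR, frame
#' type) trained on 500 frames (250 normal, 125 per lesion model) and tested
#' on 200 unseen frames (100 normal, 50 per lesion model), evaluated at the
#' default and adjusted operating points. Also records, per lesion size and
#' SNR, the channel with maximal mean normal-lesion difference (in the
#' `"max_diff"` attribute).
#'
#' @param snr_db SNR grid (dB).
#' @param n_train_normal,n_train_per_lesion,n_test_normal,n_test_per_lesion
#'   Frame budgets.
#' @param seed Master seed.
#' @param resolution Mesh preset.
#' @param budget Hyper-parameter search budget.
#' @param sorted Frame variants to run.
#' @return An `eit_study_result` tibble with one row per
#'   (SNR, frame type, operating point).
#' @export
run_noise_study <- function(snr_db = c(80, 60, 40, 20),
                            n_train_normal = 250, n_train_per_lesion = 125,
                            n_test_normal = 100, n_test_per_lesion = 50,
                            seed = 1L, resolution = "coarse", budget = 30L,
                            sorted = c(FALSE, TRUE)) {
  models <- north_train_models()
  pattern <- build_stim_pattern(16, 2)
  rows <- list()
  max_diff <- list()
  for (snr in snr_db) {
    train <- make_dataset(models, c(n_train_normal, n_train_per_lesion, n_train_per_lesion),
      snr_db = snr, seed = seed_stream(seed, paste0("noise-train-", snr)),
      resolution = resolution
    )
    test <- make_dataset(models, c(n_test_normal, n_test_per_lesion, n_test_per_lesion),
      snr_db = snr, seed = seed_stream(seed, paste0("noise-test-", snr)),
      resolution = resolution
    )
    for (srt in sorted) {
      tr <- if (srt) sort_frames(train) else train
      te <- if (srt) sort_frames(test) else test
      res <- train_eval_cells(tr, te,
        classifier_spec("linear_svm", budget = budget),
        seed = seed_stream(seed, paste0("noise-clf-", snr, "-", srt)),
        extra = list(snr_db = snr)
      )
      rows[[length(rows) + 1]] <- res$rows
    }
    for (vol in c(30, 60)) {
      nrm <- train[train$label < 0, ]
      les <- train[grepl(paste0("les=", vol, "ml@north"), train$model_id), ]
      max_diff[[length(max_diff) + 1]] <- dplyr::bind_cols(
        tibble(snr_db = snr, volume_ml = vol),
        max_diff_channel(nrm, les, pattern)
      )
    }
  }
  out <- study_result(rows, "noise", list(seed = seed, resolution = resolution))
  attr(out, "max_diff") <- dplyr::bind_rows(max_diff)
  out
}

#' Study: generalisation to unseen lesion locations
#'
#' Trained on north-location lesions only (base model, 250 normal + 125 per
#' 30/60 ml north lesion) and tested on 120 unseen normal frames plus 20
#' frames from each of the six east/south/west lesion models.
#'
#' @inheritParams run_noise_study
#' @param n_test_per_lesion Frames per off-north lesion model.
#' @return An `eit_study_result`.
#' @export
run_location_study <- function(snr_db = c(80, 60, 40, 20),
                               n_train_normal = 250, n_train_per_lesion = 125,
                               n_test_normal = 120, n_test_per_lesion = 20,
                               seed = 1L, resolution = "coarse", budget = 30L,
                               sorted = c(FALSE, TRUE)) {
  train_models <- north_train_models()
  test_models <- dplyr::bind_rows(
    make_descriptors(),
    make_descriptors(volume_ml = c(30, 60), location = c("east", "south", "west"))
  )
  rows <- list()
  for (snr in snr_db) {
    train <- make_dataset(train_models, c(n_train_normal, n_train_per_lesion, n_train_per_lesion),
      snr_db = snr, seed = seed_stream(seed, paste0("loc-train-", snr)),
      resolution = resolution
    )
    test <- make_dataset(test_models, c(n_test_normal, rep(n_test_per_lesion, 6)),
      snr_db = snr, seed = seed_stream(seed, paste0("loc-test-", snr)),
      resolution = resolution
    )
    for (srt in sorted) {
      res <- train_eval_cells(
        if (srt) sort_frames(train) else train,
        if (srt) sort_frames(test) else test,
        classifier_spec("linear_svm", budget = budget),
        seed = seed_stream(seed, paste0("loc-clf-", snr, "-", srt)),
        extra = list(snr_db = snr)
      )
      rows[[length(rows) + 1]] <- res$rows
    }
  }
  study_result(rows, "location", list(seed = seed, resolution = resolution))
}

#' Study: generalisation across lesion sizes
#'
#' Direction `"down"` trains on the 60 ml lesion at all four locations (300
#' normal + 75 frames per location) and tests sequentially on each smaller
#' size; `"up"` trains on the 5 ml lesion and tests on each larger size.
#' Each test set has 80 unseen normal frames and 20 frames per lesion
#' location. Fixed 60 dB SNR by default.
#'
#' @param direction `"down"` (train large) or `"up"` (train small).
#' @param snr_db Single SNR (dB).
#' @param test_volumes_ml Test lesion volumes (defaults depend on
#'   direction).
#' @inheritParams run_noise_study
#' @return An `eit_study_result` with one row per (test volume, frame type,
#'   operating point).
#' @export
run_size_study <- function(direction = c("down", "up"), snr_db = 60,
                           test_volumes_ml = NULL,
                           n_train_normal = 300, n_train_per_lesion = 75,
                           n_test_normal = 80, n_test_per_lesion = 20,
                           seed = 1L, resolution = "coarse", budget = 30L,
                           sorted = c(FALSE, TRUE)) {
  direction <- match.arg(direction)
  train_volume <- if (direction == "down") 60 else 5
  test_volumes_ml <- test_volumes_ml %||%
    (if (direction == "down") c(30, 20, 10, 5) else c(10, 20, 30, 60))
  train_models <- dplyr::bind_rows(
    make_descriptors(),
    make_descriptors(volume_ml = train_volume, location = LESION_LOCATIONS)
  )
  rows <- list()
  for (snr in snr_db) {
    train <- make_dataset(train_models, c(n_train_normal, rep(n_train_per_lesion, 4)),
      snr_db = snr,
      seed = seed_stream(seed, paste0("size-", direction, "-train-", snr)),
      resolution = resolution
    )
    clfs <- list()
    for (srt in sorted) {
      key <- if (srt) "sorted" else "unaltered"
      clfs[[key]] <- train_classifier(
        if (srt) sort_frames(train) else train,
        classifier_spec("linear_svm", budget = budget),
        seed = seed_stream(seed, paste0("size-", direction, "-clf-", snr, "-", srt))
      )
    }
    for (vol in test_volumes_ml) {
      test_models <- dplyr::bind_rows(
        make_descriptors(),
        make_descriptors(volume_ml = vol, location = LESION_LOCATIONS)
      )
      test <- make_dataset(test_models, c(n_test_normal, rep(n_test_per_lesion, 4)),
        snr_db = snr,
        seed = seed_stream(seed, paste0("size-", direction, "-test-", snr, "-", vol)),
        resolution = resolution
      )
      for (srt in sorted) {
        key <- if (srt) "sorted" else "unaltered"
        te <- if (srt) sort_frames(test) else test
        for (op in c("default", "adjusted")) {
          pred <- predict(clfs[[key]], te, op = op)
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble(
              snr_db = snr, train_volume_ml = train_volume, test_volume_ml = vol,
              frames = key, op = op, auc = clfs[[key]]$auc
            ),
            evaluate_predictions(te$label, pred)
          )
        }
      }
    }
  }
  study_result(rows, paste0("size_", direction),
               list(seed = seed, resolution = resolution))
}

#' Study: effect of electrode-ring positioning
#'
#' Classifiers are trained at the nominal ring height on 640 frames (320
#' normal + 40 per 30/60 ml x 4-location lesion model) and tested on frames
#' from the same tissue models with the ring shifted by +/-2 mm (40 normal
#' and 5 per lesion model per shifted ring, pooled to 80 + 80).
#'
#' @param test_offsets_mm Ring height offsets used for the test set.
#' @inheritParams run_noise_study
#' @return An `eit_study_result`.
#' @export
run_electrode_study <- function(snr_db = 60, test_offsets_mm = c(-2, 2),
                                n_train_normal = 320, n_train_per_lesion = 40,
                                n_test_normal = 40, n_test_per_lesion = 5,
                                seed = 1L, resolution = "coarse", budget = 30L,
                                sorted = c(FALSE, TRUE)) {
  train_models <- dplyr::bind_rows(
    make_descriptors(),
    make_descriptors(volume_ml = c(30, 60), location = LESION_LOCATIONS)
  )
  test_models <- dplyr::bind_rows(
    make_descriptors(height = test_offsets_mm),
    make_descriptors(height = test_offsets_mm, volume_ml = c(30, 60), location = LESION_LOCATIONS)
  )
  n_norm <- sum(test_models$label < 0)
  n_les <- sum(test_models$label > 0)
  rows <- list()
  for (snr in snr_db) {
    train <- make_dataset(train_models, c(n_train_normal, rep(n_train_per_lesion, 8)),
      snr_db = snr, seed = seed_stream(seed, paste0("elec-train-", snr)),
      resolution = resolution
    )
    test <- make_dataset(
      test_models,
      ifelse(test_models$label < 0, n_test_normal, n_test_per_lesion),
      snr_db = snr, seed = seed_stream(seed, paste0("elec-test-", snr)),
      resolution = resolution
    )
    for (srt in sorted) {
      res <- train_eval_cells(
        if (srt) sort_frames(train) else train,
        if (srt) sort_frames(test) else test,
        classifier_spec("linear_svm", budget = budget),
        seed = seed_stream(seed, paste0("elec-clf-", snr, "-", srt)),
        extra = list(snr_db = snr)
      )
      rows[[length(rows) + 1]] <- res$rows
    }
  }
  study_result(rows, "electrode", list(
    seed = seed, resolution = resolution,
    test_offsets_mm = test_offsets_mm, n_test = n_norm + n_les
  ))
}

#' Study: generalisation across head/brain anatomies
#'
#' Trains on the base anatomy (normal plus all eight 30/60 ml x 4-location
#' lesion models) and tests on lesioned and normal frames from anatomies the
#' classifier has never seen. Frame budgets and the test-anatomy grid are
#' scaled down from the full recipe (5,120 + 5,120 training frames over 80
#' anatomies) by default; balance invariants are preserved. The
#' `"anatomy_diagnostic"` attribute reports the point-biserial correlation
#' between each test model's outer-to-brain volume ratio and its predicted
#' labels.
#'
#' @param test_anatomies Tibble of `head_variant`/`brain_variant` pairs to
#'   test on (default: the 3x3 XYZ sub-grid minus the base anatomy).
#' @param n_test_normal_frames,n_test_lesion_frames Frames per test normal
#'   model and per test lesion model.
#' @inheritParams run_noise_study
#' @return An `eit_study_result`.
#' @export
run_anatomy_study <- function(snr_db = 60,
                              n_train_normal = 320, n_train_per_lesion = 40,
                              test_anatomies = NULL,
                              n_test_normal_frames = 16, n_test_lesion_frames = 2,
                              seed = 1L, resolution = "coarse", budget = 30L,
                              sorted = c(FALSE, TRUE)) {
  train_models <- dplyr::bind_rows(
    make_descriptors(),
    make_descriptors(volume_ml = c(30, 60), location = LESION_LOCATIONS)
  )
  if (is.null(test_anatomies)) {
    test_anatomies <- tidyr::expand_grid(
      head_variant = c("xyz-", "base", "xyz+"),
      brain_variant = c("xyz-", "base", "xyz+")
    ) |> dplyr::filter(!(.data$head_variant == "base" & .data$brain_variant == "base"))
  }
  test_models <- dplyr::bind_rows(lapply(seq_len(nrow(test_anatomies)), function(i) {
    dplyr::bind_rows(
      make_descriptors(
        head = test_anatomies$head_variant[i],
        brain = test_anatomies$brain_variant[i]
      ),
      make_descriptors(
        head = test_anatomies$head_variant[i],
        brain = test_anatomies$brain_variant[i],
        volume_ml = c(30, 60), location = LESION_LOCATIONS
      )
    )
  }))
  rows <- list()
  diags <- list()
  for (snr in snr_db) {
    train <- make_dataset(train_models, c(n_train_normal, rep(n_train_per_lesion, 8)),
      snr_db = snr, seed = seed_stream(seed, paste0("anat-train-", snr)),
      resolution = resolution
    )
    test <- make_dataset(
      test_models,
      ifelse(test_models$label < 0, n_test_normal_frames, n_test_lesion_frames),
      snr_db = snr, seed = seed_stream(seed, paste0("anat-test-", snr)),
      resolution = resolution
    )
    for (srt in sorted) {
      te <- if (srt) sort_frames(test) else test
      res <- train_eval_cells(
        if (srt) sort_frames(train) else train, te,
        classifier_spec("linear_svm", budget = budget),
        seed = seed_stream(seed, paste0("anat-clf-", snr, "-", srt)),
        extra = list(snr_db = snr)
      )
      rows[[length(rows) + 1]] <- res$rows
      pred <- predict(res$clf, te, op = "default")
      ratio <- volume_ratio_by_model(te$model_id)
      diags[[length(diags) + 1]] <- tibble(
        snr_db = snr, frames = if (srt) "sorted" else "unaltered",
        ratio_label_correlation = suppressWarnings(cor(ratio, pred)),
        frac_normal_when_ratio_high = mean(pred[ratio > ratio_base()] < 0)
      )
    }
  }
  out <- study_result(rows, "anatomy", list(seed = seed, resolution = resolution))
  attr(out, "anatomy_diagnostic") <- dplyr::bind_rows(diags)
  out
}

# Outer-to-brain tissue volume ratio for a model id; used by the anatomy
# diagnostic. Ellipsoid volumes follow from the semi-axis products.
volume_ratio_by_model <- function(model_ids) {
  head_v <- sub("^h=([^;]+);.*", "\\1", model_ids)
  brain_v <- sub("^h=[^;]+;b=([^;]+);.*", "\\1", model_ids)
  vapply(seq_along(model_ids), function(i) {
    hs <- variant_scale(head_v[i])
    bs <- variant_scale(brain_v[i])
    vh <- prod(BASE_HEAD_SEMI_AXES * hs)
    vb <- prod(BASE_BRAIN_SEMI_AXES * bs)
    (vh - vb) / vb
  }, numeric(1))
}

ratio_base <- function() {
  vh <- prod(BASE_HEAD_SEMI_AXES)
  vb <- prod(BASE_BRAIN_SEMI_AXES)
  (vh - vb) / vb
}

# Scaled-down pooled model grid: head/brain in {-5% XYZ, base, +5% XYZ} x 3
# ring heights (27 normal models) plus their 8 lesion variants (216 lesion
# models), mirroring the structure of the full 243/1944 grid.
pooled_grid <- function() {
  sub <- c("xyz-", "base", "xyz+")
  dplyr::bind_rows(
    enumerate_models(heights = 3, head_variants = sub, brain_variants = sub),
    enumerate_models(heights = 3, with_lesions = TRUE,
                     head_variants = sub, brain_variants = sub)
  )
}

pooled_dataset <- function(snr_db, n_per_normal, n_per_lesion, sorted, seed,
                           resolution, grid = pooled_grid()) {
  make_dataset(
    grid,
    ifelse(grid$label < 0, n_per_normal, n_per_lesion),
    snr_db = snr_db, sorted = sorted, seed = seed, resolution = resolution
  )
}

#' Study: pooled overall benchmark over the model grid
#'
#' Trains and tests linear SVMs on frames pooled over the whole model grid
#' (normals and all 30/60 ml lesion variants), class-balanced with an equal
#' number of frames per model within each class. The default grid is the
#' documented scaled-down 27-normal / 216-lesion sub-grid with 32/4 training
#' and 8/1 test frames per normal/lesion model (864 + 864 train, 216 + 216
#' test).
#'
#' @param n_train_per_normal,n_train_per_lesion,n_test_per_normal,n_test_per_lesion
#'   Frames per model; normal and lesion counts must keep the classes
#'   balanced (n_normal_models x per-normal = n_lesion_models x per-lesion).
#' @param grid Model-descriptor tibble defining the pooled grid (default: the
#'   documented scaled-down sub-grid).
#' @inheritParams run_noise_study
#' @return An `eit_study_result`.
#' @export
run_overall_study <- function(snr_db = c(80, 60, 40, 20),
                              n_train_per_normal = 32, n_train_per_lesion = 4,
                              n_test_per_normal = 8, n_test_per_lesion = 1,
                              seed = 1L, resolution = "coarse", budget = 12L,
                              sorted = c(FALSE, TRUE), grid = pooled_grid()) {
  rows <- list()
  for (snr in snr_db) {
    train <- pooled_dataset(snr, n_train_per_normal, n_train_per_lesion,
      sorted = FALSE, seed = seed_stream(seed, paste0("overall-train-", snr)),
      resolution = resolution, grid = grid
    )
    test <- pooled_dataset(snr, n_test_per_normal, n_test_per_lesion,
      sorted = FALSE, seed = seed_stream(seed, paste0("overall-test-", snr)),
      resolution = resolution, grid = grid
    )
    for (srt in sorted) {
      res <- train_eval_cells(
        if (srt) sort_frames(train) else train,
        if (srt) sort_frames(test) else test,
        classifier_spec("linear_svm", budget = budget),
        seed = seed_stream(seed, paste0("overall-clf-", snr, "-", srt)),
        extra = list(snr_db = snr)
      )
      rows[[length(rows) + 1]] <- res$rows
    }
  }
  study_result(rows, "overall", list(seed = seed, resolution = resolution))
}

#' Three-classifier comparison on the pooled dataset
#'
#' For each classifier kind and SNR, a ten-fold 90/10 scheme on the pooled
#' (sorted-frame) dataset: the data are split into ten stratified folds;
#' SVM hyper-parameters are optimised once per cell on the first fold's
#' training split (ten-fold CV Bayesian search) and reused for the
#' remaining folds; each fold's held-out 10% is classified at the default
#' operating point. The NN repeats its 70/15/15 internal protocol per fold
#' and is evaluated on the same held-out folds. Reports mean and standard
#' deviation of sensitivity, specificity and accuracy across the ten folds.
#'
#' @param kinds Classifier kinds to compare.
#' @param n_folds Number of 90/10 splits (default 10).
#' @param n_per_normal,n_per_lesion Frames per normal/lesion model in the
#'   pooled set (defaults give 432 + 432 = 864 frames on the scaled-down
#'   grid).
#' @param standardise Z-score channels (training statistics per fold);
#'   recommended, since the kernel-scale search range assumes order-one
#'   features.
#' @inheritParams run_overall_study
#' @return A tibble of class `eit_comparison` with mean +/- sd metrics per
#'   (kind, SNR); per-fold results in the `"folds"` attribute.
#' @export
run_classifier_comparison <- function(snr_db = c(80, 60, 40, 20),
                                      kinds = c("linear_svm", "rbf_svm", "nn"),
                                      n_folds = 10, n_per_normal = 16, n_per_lesion = 2,
                                      seed = 1L, resolution = "coarse", budget = 8L,
                                      standardise = TRUE, grid = pooled_grid()) {
  fold_rows <- list()
  for (snr in snr_db) {
    data <- pooled_dataset(snr, n_per_normal, n_per_lesion,
      sorted = TRUE, seed = seed_stream(seed, paste0("cmp-data-", snr)),
      resolution = resolution, grid = grid
    )
    X <- frame_matrix(data)
    y01 <- as.integer(data$label > 0)
    old <- .Random.seed_save()
    set.seed(seed_stream(seed, paste0("cmp-folds-", snr)))
    fold <- make_folds(y01, n_folds)
    .Random.seed_restore(old)
    for (kind in kinds) {
      fold_rows[[length(fold_rows) + 1]] <- comparison_cell(
        X, y01, fold, kind, snr,
        budget = budget, standardise = standardise,
        seed = seed_stream(seed, paste0("cmp-", kind, "-", snr))
      )
    }
  }
  folds <- dplyr::bind_rows(fold_rows)
  out <- folds |>
    dplyr::group_by(.data$kind, .data$snr_db) |>
    dplyr::summarise(dplyr::across(
      c("sensitivity", "specificity", "accuracy"),
      list(mean = mean, sd = sd)
    ), .groups = "drop")
  attr(out, "folds") <- folds
  class(out) <- c("eit_comparison", class(out))
  out
}

comparison_cell <- function(X, y01, fold, kind, snr, budget, standardise, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_folds <- max(fold)
  zscore <- function(M, centre, sdev) sweep(sweep(M, 2, centre), 2, sdev, "/")

  hyper <- NULL
  if (kind != "nn") {
    tr1 <- fold != 1L
    X1 <- X[tr1, , drop = FALSE]
    y1 <- y01[tr1]
    if (standardise) {
      X1 <- zscore(X1, colMeans(X1), pmax(apply(X1, 2, sd), 1e-15))
    }
    inner <- make_folds(y1, 10L)
    cv_err <- function(par) {
      errs <- vapply(1:10, function(f) {
        tr <- inner != f
        fit <- svm_fit(X1[tr, , drop = FALSE], y1[tr], kind,
          cost = 10^par[1],
          kernel_scale = if (kind == "rbf_svm") 10^par[2] else NULL
        )
        mean(predict(fit, X1[!tr, , drop = FALSE]) != factor(y1[!tr], levels = c(0, 1)))
      }, numeric(1))
      mean(errs)
    }
    d <- if (kind == "rbf_svm") 2L else 1L
    anchor <- if (d == 2L) c(0, log10(sqrt(ncol(X1)))) else 0
    bo <- bayes_minimise(cv_err,
      lower = rep(-3, d), upper = rep(3, d),
      n_total = budget, n_init = min(max(4L, budget %/% 3L), budget),
      seed = seed + 1L, init_points = anchor
    )
    hyper <- list(
      cost = 10^bo$par[1],
      kernel_scale = if (d == 2L) 10^bo$par[2] else NULL
    )
  }

  rows <- lapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    ytr <- y01[tr]
    if (standardise) {
      ctr <- colMeans(Xtr)
      sdev <- pmax(apply(Xtr, 2, sd), 1e-15)
      Xtr <- zscore(Xtr, ctr, sdev)
      Xte <- zscore(Xte, ctr, sdev)
    }
    if (kind == "nn") {
      nn <- train_nn(Xtr, ytr, classifier_spec("nn"))
      p <- as.vector(predict(nn$model, Xte))
    } else {
      fit <- svm_fit(Xtr, ytr, kind, hyper$cost, hyper$kernel_scale)
      sc_tr <- svm_scores(fit, Xtr, y01 = ytr)
      platt <- platt_fit(sc_tr$scores, ytr)
      p <- platt_apply(platt, svm_scores(fit, Xte, orientation = sc_tr$orientation)$scores)
    }
    pred <- ifelse((1 - p) >= 0.5, -1, 1) # default operating point
    dplyr::bind_cols(
      tibble(kind = kind, snr_db = snr, fold = f),
      evaluate_predictions(ifelse(y01[!tr] == 1, 1, -1), pred)
    )
  })
  dplyr::bind_rows(rows)
}
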
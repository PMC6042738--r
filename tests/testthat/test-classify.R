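small_spec <- function(kind = "linear_svm", ...) {
  classifier_spec(kind, budget = 6, ...)
}

test_that("a separable problem trains to AUC 1 with sensible hyper-parameters", {
  d <- blob_dataset(15)
  clf <- train_classifier(d, small_spec(), seed = 1)
  expect_equal(clf$auc, 1)
  expect_true(clf$hyper$cost >= 1e-3 && clf$hyper$cost <= 1e3)
  pred <- predict(clf, d, op = "default")
  expect_equal(pred, d$label)
})

test_that("training is bit-reproducible under a fixed seed", {
  d <- blob_dataset(10)
  c1 <- train_classifier(d, small_spec(), seed = 42)
  c2 <- train_classifier(d, small_spec(), seed = 42)
  expect_identical(c1$hyper, c2$hyper)
  expect_identical(c1$train_posterior, c2$train_posterior)
  expect_identical(c1$platt, c2$platt)
})

test_that("degenerate training inputs are rejected", {
  d <- blob_dataset(8)
  d_pos <- d[d$label > 0, ]
  expect_error(train_classifier(d_pos, small_spec(), seed = 1), "both labels")
  mixed <- d
  mixed$sorted[1] <- TRUE
  expect_error(train_classifier(mixed, small_spec(), seed = 1), "mixes")
})

test_that("operating points implement the stated threshold and tie rules", {
  expect_equal(default_threshold(), list(tau = 0.5, tie = "-1"))

  # default: P(-1) >= 0.5 classifies normal, so a 50/50 case goes to -1;
  # adjusted with tau = 0.5: the same case goes to +1
  expect_equal(classify_at(0.5, 0.5, tie_bleed = FALSE), -1)
  expect_equal(classify_at(0.5, 0.5, tie_bleed = TRUE), 1)
  expect_equal(classify_at(0.49, 0.5, tie_bleed = FALSE), -1)
  expect_equal(classify_at(0.51, 0.5, tie_bleed = FALSE), 1)
  expect_equal(classify_at(0, 0.5, tie_bleed = FALSE), -1) # P(-1) = 1
})

test_that("the adjusted threshold is the first training-ROC point with TPR 1", {
  # enumeration oracle: smallest tau >= 0.5 on P(-1) giving training TPR 1
  oracle_tau <- function(p_pos, labels) {
    q <- 1 - p_pos
    cands <- sort(unique(c(0.5, q[q >= 0.5]))) # the threshold rises from 0.5
    for (tau in cands) {
      pred <- ifelse(q > tau, -1, 1)
      if (all(pred[labels > 0] == 1)) {
        return(tau)
      }
    }
    1
  }
  fake_clf <- function(p_pos, labels) {
    structure(list(train_posterior = p_pos, train_labels = labels),
      class = "eit_classifier"
    )
  }
  # separable posteriors: tau stays at 0.5 and training sens = spec = 1
  clf <- fake_clf(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  thr <- adjusted_threshold(clf)
  expect_equal(thr$tau, oracle_tau(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1)))
  expect_equal(thr$tau, 0.5)
  expect_equal(thr$tie, "+1")
  pred <- classify_at(c(0.9, 0.8, 0.2, 0.1), thr$tau, tie_bleed = TRUE)
  expect_equal(evaluate_predictions(c(1, 1, -1, -1), pred)$sensitivity, 1)
  expect_equal(evaluate_predictions(c(1, 1, -1, -1), pred)$specificity, 1)

  # overlapping posteriors require raising tau; agree with the oracle
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(30)
    y <- sample(c(-1, 1), 30, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) next
    thr <- adjusted_threshold(fake_clf(p, y))
    expect_equal(thr$tau, oracle_tau(p, y))
    pred <- classify_at(p, thr$tau, tie_bleed = TRUE)
    expect_equal(evaluate_predictions(y, pred)$sensitivity, 1)
  }

  # no separation at all: everything is called a bleed
  thr <- adjusted_threshold(fake_clf(c(0.01, 0.99), c(1, -1)))
  pred <- classify_at(c(0.01, 0.99), thr$tau, tie_bleed = TRUE)
  expect_equal(pred, c(1, 1))
})

test_that("raising the threshold never trades sensitivity down or specificity up", {
  set.seed(8)
  for (rep in 1:25) {
    p <- runif(40)
    y <- sample(c(-1, 1), 40, replace = TRUE)
    taus <- sort(runif(10, 0.5, 1))
    evals <- lapply(taus, function(tau) {
      evaluate_predictions(y, classify_at(p, tau, tie_bleed = TRUE))
    })
    sens <- vapply(evals, function(e) e$sensitivity, numeric(1))
    spec <- vapply(evals, function(e) e$specificity, numeric(1))
    expect_true(all(diff(sens[!is.na(sens)]) >= 0))
    expect_true(all(diff(spec[!is.na(spec)]) <= 0))
  }
})

test_that("moving default to adjusted never flips a bleed call back to normal", {
  d <- blob_dataset(12, gap = 2)
  clf <- train_classifier(d, small_spec(), seed = 2)
  p_def <- predict(clf, d, op = "default")
  p_adj <- predict(clf, d, op = "adjusted")
  expect_true(all(p_adj[p_def == 1] == 1))
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 50
    scores <- round(runif(n), 2) # coarse rounding forces ties
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(auc_trapezoid(roc_curve(scores, y)), mw_auc(scores, y),
      tolerance = 1e-9
    )
  }
  # and against an independent library implementation
  set.seed(22)
  scores <- runif(60)
  y <- sample(c(-1, 1), 60, replace = TRUE)
  expect_equal(
    auc_trapezoid(roc_curve(scores, y)),
    as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE, direction = "<"))),
    tolerance = 1e-9
  )
})

test_that("posterior calibration is order-preserving in the decision scores", {
  d <- blob_dataset(12, gap = 1.5)
  clf <- train_classifier(d, small_spec(), seed = 5)
  sc <- eitbleed:::svm_scores(clf$model, frame_matrix(d), orientation = clf$orientation)
  p <- predict(clf, d, op = "posterior")
  o <- order(sc$scores)
  expect_true(all(diff(p[o]) >= 0)) # monotone non-decreasing
  if (identical(clf$platt$kind, "sigmoid")) {
    expect_equal(cor(rank(sc$scores), rank(p)), 1)
  }
})

test_that("separated calibration scores yield the 0.5 plateau inside the gap", {
  platt <- eitbleed:::platt_fit(c(-2, -1, 1, 2), c(0, 0, 1, 1))
  expect_identical(platt$kind, "step")
  expect_equal(
    eitbleed:::platt_apply(platt, c(-3, -1, 0, 1, 3)),
    c(0, 0, 0.5, 1, 1)
  )
  # overlapping scores fall back to a sigmoid
  platt2 <- eitbleed:::platt_fit(c(-2, 0.5, -0.5, 2), c(0, 0, 1, 1))
  expect_identical(platt2$kind, "sigmoid")
})

test_that("evaluate_predictions counts the confusion matrix with +1 positive", {
  e <- evaluate_predictions(c(1, 1, -1, -1), c(1, -1, -1, -1))
  expect_equal(e$tp, 1)
  expect_equal(e$fn, 1)
  expect_equal(e$tn, 2)
  expect_equal(e$fp, 0)
  expect_equal(e$sensitivity, 0.5)
  expect_equal(e$specificity, 1)
  expect_equal(e$accuracy, 0.75)

  all_good <- evaluate_predictions(c(1, -1), c(1, -1))
  expect_equal(all_good$sensitivity, 1)
  expect_equal(all_good$specificity, 1)

  all_pos <- evaluate_predictions(c(1, -1), c(1, 1))
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)

  expect_error(evaluate_predictions(c(1, -1), 1), "length")
})

test_that("prediction guards the sorted/unaltered convention and empty input", {
  d <- blob_dataset(8)
  clf <- train_classifier(d, small_spec(), seed = 1)
  expect_error(predict(clf, sort_frames(d)), "mismatch")
  expect_length(predict(clf, d[0, ], op = "default"), 0)
})

test_that("RBF SVM and neural network kinds train and separate the blobs", {
  d <- blob_dataset(15, gap = 6)
  rbf <- train_classifier(d, classifier_spec("rbf_svm", budget = 8, standardise = TRUE),
    seed = 3
  )
  expect_equal(predict(rbf, d, op = "default"), d$label)
  expect_gt(rbf$auc, 0.99)

  nn <- train_classifier(d, classifier_spec("nn"), seed = 3)
  expect_equal(nn$spec$nn_hidden, 10L)
  expect_gt(nn$auc, 0.99)
  expect_gt(mean(predict(nn, d, op = "default") == d$label), 0.9)
})

test_that("tidy and glance summarise a trained classifier", {
  d <- blob_dataset(8)
  clf <- train_classifier(d, small_spec(), seed = 1)
  td <- tidy(clf)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_true("cost" %in% td$term)
  gl <- glance(clf)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$kind, "linear_svm")
  expect_equal(gl$n_train, 16)
})
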
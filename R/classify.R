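# Frame classifiers: linear-kernel and RBF-kernel SVMs (e1071/libsvm) with
# Bayesian hyper-parameter search over 10-fold cross-validated error and
# Platt-style posterior calibration, and a single-hidden-layer neural
# network (nnet). Operating points act on the calibrated posterior
# probability of the "normal" class: the default point classifies normal
# when P(-1) >= 0.5 (ties to normal); the sensitivity-maximising adjusted
# point raises the threshold to the first training-ROC point with true
# positive rate 1.0 and flips the tie rule to bleed.

#' Specify a frame classifier
#'
#' @param kind `"linear_svm"`, `"rbf_svm"` or `"nn"`.
#' @param cv_folds Folds for the hyper-parameter search (default 10).
#' @param budget Bayesian-search evaluation budget (default 30; ignored for
#'   `"nn"`).
#' @param nn_hidden Hidden units for the neural network (default 10).
#' @param nn_split Train/validation/test fractions for the network's
#'   internal split (must sum to 1).
#' @param standardise Z-score channels using training statistics (default
#'   `FALSE`: features enter as raw volts).
#' @return An object of class `eit_classifier_spec`.
#' @export
classifier_spec <- function(kind = c("linear_svm", "rbf_svm", "nn"),
                            cv_folds = 10, budget = 30, nn_hidden = 10,
                            nn_split = c(0.70, 0.15, 0.15),
                            standardise = FALSE) {
  kind <- match.arg(kind)
  if (cv_folds < 2) abort("cv_folds must be at least 2")
  if (abs(sum(nn_split) - 1) > 1e-8) abort("nn_split must sum to 1")
  structure(
    list(
      kind = kind, cv_folds = as.integer(cv_folds), budget = as.integer(budget),
      nn_hidden = as.integer(nn_hidden), nn_split = nn_split,
      standardise = isTRUE(standardise)
    ),
    class = "eit_classifier_spec"
  )
}

make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

svm_fit <- function(X, y01, kind, cost, kernel_scale = NULL) {
  yf <- factor(y01, levels = c(0, 1))
  if (kind == "linear_svm") {
    e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE)
  } else {
    e1071::svm(X, yf,
      kernel = "radial", cost = cost,
      gamma = 1 / (2 * kernel_scale^2), scale = FALSE
    )
  }
}

# Decision scores oriented so that larger means "more likely bleed (+1)".
svm_scores <- function(fit, X, orientation = NULL, y01 = NULL) {
  dv <- unname(attr(predict(fit, X, decision.values = TRUE), "decision.values")[, 1])
  if (is.null(orientation)) {
    stopifnot(!is.null(y01))
    orientation <- if (mean(dv[y01 == 1]) >= mean(dv[y01 == 0])) 1 else -1
  }
  list(scores = orientation * dv, orientation = orientation)
}

# Posterior calibration of decision scores. Overlapping classes get a
# Platt sigmoid (regularised targets). Perfectly separated classes get a
# step map that is 0 below the normal scores, 1 above the bleed scores and
# exactly 0.5 inside the separation gap: the sigmoid's maximum-likelihood
# slope diverges there, and the 0.5 plateau is what gives the adjusted
# operating point its bite — cases falling between the training clusters
# become 50/50 ties that the flipped tie rule classifies as bleeds.
platt_fit <- function(scores, y01) {
  lo <- max(scores[y01 == 0])
  hi <- min(scores[y01 == 1])
  if (hi > lo) {
    return(list(kind = "step", lo = lo, hi = hi))
  }
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  t <- ifelse(y01 == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    p <- stats::plogis(par[1] * scores + par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  fit <- optim(c(1 / max(sd(scores), 1e-12), 0), nll, method = "BFGS")
  list(kind = "sigmoid", a = fit$par[1], b = fit$par[2])
}

platt_apply <- function(platt, scores) {
  if (identical(platt$kind, "step")) {
    ifelse(scores <= platt$lo, 0, ifelse(scores >= platt$hi, 1, 0.5))
  } else {
    stats::plogis(platt$a * scores + platt$b)
  }
}

#' ROC curve of scores against labels
#'
#' @param posterior Scores (e.g. calibrated posterior P(+1)); larger means
#'   more likely positive.
#' @param labels True labels in {-1, +1}.
#' @return A tibble with `threshold`, `tpr`, `fpr`, a monotone step curve
#'   from (0,0) to (1,1).
#' @export
roc_curve <- function(posterior, labels) {
  stopifnot(length(posterior) == length(labels))
  o <- order(posterior, decreasing = TRUE)
  y <- labels[o] > 0
  s <- posterior[o]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE) # collapse tied scores
  tibble(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp[last] / max(sum(y), 1)),
    fpr = c(0, fp[last] / max(sum(!y), 1))
  )
}

#' Area under an ROC curve (trapezoidal rule)
#'
#' @param roc A tibble from [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' The default operating point
#'
#' Classify as normal (-1) when the posterior probability of the normal
#' class is at least 0.5; ties go to normal.
#'
#' @return A list with `tau = 0.5` and `tie = "-1"`.
#' @export
default_threshold <- function() list(tau = 0.5, tie = "-1")

#' The sensitivity-maximising adjusted operating point
#'
#' The threshold on P(-1) of the first training-ROC point (as the threshold
#' rises from 0.5) with true positive rate 1.0 and minimal false positive
#' rate; the tie rule flips to bleed, so a case with P(-1) equal to the
#' threshold is classified +1.
#'
#' @param clf A trained `eit_classifier`.
#' @return A list with `tau` (in \[0.5, 1\]) and `tie = "+1"`.
#' @export
adjusted_threshold <- function(clf) {
  q_pos <- 1 - clf$train_posterior[clf$train_labels > 0]
  list(tau = max(0.5, max(q_pos)), tie = "+1")
}

#' Train a frame classifier
#'
#' SVM kinds: hyper-parameters (box constraint; kernel scale for RBF, both
#' searched log-uniformly in 1e-3..1e3) are chosen to minimise k-fold
#' cross-validated misclassification via Bayesian optimisation; the
#' posterior map is a Platt sigmoid fitted to cross-validated decision
#' scores at the selected hyper-parameters; the training ROC/AUC comes from
#' the calibrated scores of the final model on the training data. The NN
#' kind trains a single hidden layer of `nn_hidden` units on an internal
#' 70/15/15 split, selecting its stopping iteration on the validation slice.
#'
#' @param data A frame dataset tibble with both labels present.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed; training is bit-reproducible given (data, spec,
#'   seed).
#' @return An object of class `eit_classifier`.
#' @export
train_classifier <- function(data, spec = classifier_spec(), seed = 1L) {
  stopifnot(inherits(spec, "eit_classifier_spec"))
  X <- frame_matrix(data)
  y <- data$label
  if (length(unique(y)) < 2L) abort("training data must contain both labels (+1 and -1)")
  y01 <- as.integer(y > 0)
  sorted_flag <- isTRUE(all(data$sorted))
  if (!sorted_flag && any(data$sorted)) {
    abort("training data mixes sorted and unaltered frames")
  }

  scale_centre <- scale_sd <- NULL
  if (spec$standardise) {
    scale_centre <- colMeans(X)
    scale_sd <- pmax(apply(X, 2, sd), 1e-15)
    X <- sweep(sweep(X, 2, scale_centre), 2, scale_sd, "/")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  if (spec$kind == "nn") {
    clf <- train_nn(X, y01, spec)
  } else {
    clf <- train_svm(X, y01, spec, seed)
  }

  clf$kind <- spec$kind
  clf$spec <- spec
  clf$seed <- seed
  clf$sorted <- sorted_flag
  clf$n_train <- nrow(X)
  clf$scale_centre <- scale_centre
  clf$scale_sd <- scale_sd
  clf$train_labels <- y
  # ROC/AUC from the (rank-equivalent) decision scores: calibration cannot
  # change ranks but its step branch can introduce ties
  clf$roc <- roc_curve(clf$train_scores, y)
  clf$auc <- auc_trapezoid(clf$roc)
  class(clf) <- "eit_classifier"
  clf
}

train_svm <- function(X, y01, spec, seed) {
  fold <- make_folds(y01, spec$cv_folds)
  cv_error <- function(par) {
    errs <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- fold != f
      if (all(tr) || length(unique(y01[tr])) < 2L) {
        return(NA_real_)
      }
      fit <- svm_fit(X[tr, , drop = FALSE], y01[tr], spec$kind,
        cost = 10^par[1],
        kernel_scale = if (spec$kind == "rbf_svm") 10^par[2] else NULL
      )
      pred <- predict(fit, X[!tr, , drop = FALSE])
      mean(pred != factor(y01[!tr], levels = c(0, 1)))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }
  d <- if (spec$kind == "rbf_svm") 2L else 1L
  # anchor the search with the standard heuristics (unit box constraint;
  # kernel scale ~ sqrt(n_features) for RBF)
  anchor <- if (d == 2L) c(0, log10(sqrt(ncol(X)))) else 0
  bo <- bayes_minimise(cv_error,
    lower = rep(-3, d), upper = rep(3, d),
    n_total = spec$budget, n_init = min(max(4L, spec$budget %/% 3L), spec$budget),
    seed = seed + 1L, init_points = anchor
  )
  cost <- 10^bo$par[1]
  kernel_scale <- if (d == 2L) 10^bo$par[2] else NA_real_

  fit <- svm_fit(X, y01, spec$kind, cost, kernel_scale)
  sc <- svm_scores(fit, X, y01 = y01)

  # Cross-validated decision scores at the selected hyper-parameters give a
  # less optimistic basis for the Platt sigmoid.
  cv_scores <- rep(NA_real_, nrow(X))
  for (f in seq_len(spec$cv_folds)) {
    tr <- fold != f
    if (all(tr) || length(unique(y01[tr])) < 2L) next
    ffit <- svm_fit(X[tr, , drop = FALSE], y01[tr], spec$kind, cost, kernel_scale)
    # orient each fold's scores by its own training portion
    o_tr <- svm_scores(ffit, X[tr, , drop = FALSE], y01 = y01[tr])
    cv_scores[!tr] <- svm_scores(ffit, X[!tr, , drop = FALSE],
      orientation = o_tr$orientation
    )$scores
  }
  use <- !is.na(cv_scores)
  platt <- platt_fit(cv_scores[use], y01[use])
  list(
    model = fit, orientation = sc$orientation,
    hyper = list(cost = cost, kernel_scale = kernel_scale),
    cv_error = bo$value, platt = platt, search = bo$history,
    train_scores = sc$scores,
    train_posterior = platt_apply(platt, sc$scores)
  )
}

train_nn <- function(X, y01, spec) {
  n <- nrow(X)
  idx <- sample.int(n)
  n_tr <- round(spec$nn_split[1] * n)
  n_va <- round(spec$nn_split[2] * n)
  i_tr <- idx[seq_len(n_tr)]
  i_va <- idx[n_tr + seq_len(n_va)]
  candidates <- c(40L, 80L, 160L)
  fits <- lapply(candidates, function(m) {
    nnet::nnet(X[i_tr, , drop = FALSE], y01[i_tr],
      size = spec$nn_hidden,
      entropy = TRUE, decay = 1e-3, maxit = m, trace = FALSE,
      MaxNWts = 50000
    )
  })
  val_err <- vapply(fits, function(f) {
    mean((predict(f, X[i_va, , drop = FALSE]) >= 0.5) != (y01[i_va] == 1))
  }, numeric(1))
  best <- fits[[which.min(val_err)]]
  list(
    model = best, orientation = 1,
    hyper = list(maxit = candidates[which.min(val_err)], hidden = spec$nn_hidden),
    cv_error = min(val_err), platt = NULL,
    train_scores = as.vector(predict(best, X)),
    train_posterior = as.vector(predict(best, X))
  )
}

classifier_posterior <- function(clf, X) {
  if (nrow(X) == 0L) {
    return(numeric(0))
  }
  if (!is.null(clf$scale_centre)) {
    X <- sweep(sweep(X, 2, clf$scale_centre), 2, clf$scale_sd, "/")
  }
  if (clf$kind == "nn") {
    as.vector(predict(clf$model, X))
  } else {
    sc <- svm_scores(clf$model, X, orientation = clf$orientation)
    platt_apply(clf$platt, sc$scores)
  }
}

#' Classify frames at an operating point
#'
#' @param object A trained `eit_classifier`.
#' @param data A frame dataset tibble with the same sorted/unaltered
#'   convention as the training data (mismatch is an error).
#' @param op `"default"` (P(-1) >= 0.5 classifies normal, ties to normal) or
#'   `"adjusted"` (raised threshold, ties to bleed); or `"posterior"` to
#'   return the calibrated posterior P(+1).
#' @param ... Unused.
#' @return Numeric vector of labels in {-1, +1} (or posteriors).
#' @export
predict.eit_classifier <- function(object, data, op = c("default", "adjusted", "posterior"), ...) {
  op <- match.arg(op)
  if (nrow(data) > 0L && any(data$sorted != object$sorted)) {
    abort(paste0(
      "frame pre-processing mismatch: model trained on ",
      if (object$sorted) "sorted" else "unaltered",
      " frames but input differs"
    ))
  }
  p <- classifier_posterior(object, frame_matrix(data))
  if (op == "posterior") {
    return(p)
  }
  q <- 1 - p
  if (op == "default") {
    thr <- default_threshold()
    ifelse(q >= thr$tau, -1, 1)
  } else {
    thr <- adjusted_threshold(object)
    ifelse(q > thr$tau, -1, 1)
  }
}

#' Confusion-matrix summary of predictions
#'
#' The bleed class (+1) is the positive class: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/n.
#'
#' @param y_true,y_pred Label vectors in {-1, +1} of equal length.
#' @return A one-row tibble with counts and rates.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("label vectors differ in length")
  tp <- sum(y_true > 0 & y_pred > 0)
  fn <- sum(y_true > 0 & y_pred < 0)
  tn <- sum(y_true < 0 & y_pred < 0)
  fp <- sum(y_true < 0 & y_pred > 0)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / max(length(y_true), 1L)
  )
}

#' @export
print.eit_classifier <- function(x, ...) {
  cat(sprintf(
    "<eit_classifier> %s trained on %d frames (%s), training AUC %.4f\n",
    x$kind, x$n_train, if (x$sorted) "sorted" else "unaltered", x$auc
  ))
  if (x$kind != "nn") {
    cat(sprintf(
      "  box constraint %.4g%s, 10-fold CV error %.4f\n",
      x$hyper$cost,
      if (!is.na(x$hyper$kernel_scale)) sprintf(", kernel scale %.4g", x$hyper$kernel_scale) else "",
      x$cv_error
    ))
  }
  invisible(x)
}

#' @rdname tidy.eit_classifier
#' @method tidy eit_classifier
#' @export
tidy.eit_classifier <- function(x, ...) {
  sigmoid <- identical(x$platt$kind, "sigmoid")
  tibble(
    term = c("cost", "kernel_scale", "platt_a", "platt_b", "adjusted_tau"),
    estimate = c(
      x$hyper$cost %||% NA_real_,
      x$hyper$kernel_scale %||% NA_real_,
      if (sigmoid) x$platt$a else NA_real_,
      if (sigmoid) x$platt$b else NA_real_,
      adjusted_threshold(x)$tau
    )
  )
}

#' Tidiers for trained frame classifiers
#'
#' `tidy()` returns hyper-parameters and calibration constants; `glance()` a
#' one-row model summary.
#'
#' @param x An `eit_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @method glance eit_classifier
#' @export
glance.eit_classifier <- function(x, ...) {
  tibble(
    kind = x$kind, n_train = x$n_train, sorted = x$sorted,
    auc = x$auc, cv_error = x$cv_error %||% NA_real_
  )
}
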
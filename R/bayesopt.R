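# Minimal Bayesian optimiser for the SVM hyper-parameter search: a Gaussian
# process surrogate (squared-exponential kernel on inputs rescaled to the
# unit cube) with expected-improvement acquisition over a Latin-hypercube
# candidate set. Deterministic given the seed.

gp_fit <- function(X, y, lengthscale = 0.25, nugget = 1e-6) {
  y0 <- mean(y)
  ys <- sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  yc <- (y - y0) / ys
  d2 <- as.matrix(dist(X))^2
  K <- exp(-d2 / (2 * lengthscale^2)) + diag(nugget + 1e-4, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, yc, transpose = TRUE))
  list(X = X, L = L, alpha = alpha, y0 = y0, ys = ys, ls = lengthscale)
}

gp_predict <- function(gp, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(gp$X^2), "+") - 2 * Xnew %*% t(gp$X)
  Ks <- exp(-pmax(d2, 0) / (2 * gp$ls^2))
  mu <- as.vector(Ks %*% gp$alpha)
  v <- backsolve(gp$L, t(Ks), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = mu * gp$ys + gp$y0, sd = sqrt(s2) * gp$ys)
}

expected_improvement <- function(mu, s, best) {
  z <- (best - mu) / s
  (best - mu) * pnorm(z) + s * dnorm(z)
}

#' Minimise a function by Gaussian-process Bayesian optimisation
#'
#' @param fn Function of a numeric vector (length = number of dimensions)
#'   returning a scalar objective to minimise.
#' @param lower,upper Numeric bounds per dimension.
#' @param n_total Total evaluation budget (including the initial design).
#' @param n_init Size of the Latin-hypercube initial design.
#' @param seed Integer seed (design and candidate draws are reproducible).
#' @param init_points Optional matrix of points (original units, one row per
#'   point) always evaluated as part of the initial design — used to anchor
#'   the search with known-good heuristics.
#' @return A list with `par`, `value`, and the evaluation `history` tibble.
#' @export
bayes_minimise <- function(fn, lower, upper, n_total = 30, n_init = 8, seed = 1L,
                           init_points = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, n_init >= 2, n_total >= n_init)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  X <- lhs::maximinLHS(n_init, d)
  if (!is.null(init_points)) {
    anchors <- t((t(rbind(init_points)) - lower) / (upper - lower))
    X <- rbind(pmin(pmax(anchors, 0), 1), X)
  }
  to_par <- function(u) lower + u * (upper - lower)
  y <- apply(X, 1, function(u) fn(to_par(u)))
  for (it in seq_len(n_total - n_init)) {
    gp <- gp_fit(X, y)
    cand <- rbind(lhs::randomLHS(256, d),
                  pmin(pmax(matrix(X[which.min(y), ], 32, d, byrow = TRUE) +
                              matrix(rnorm(32 * d, sd = 0.05), 32, d), 0), 1))
    pr <- gp_predict(gp, cand)
    ei <- expected_improvement(pr$mean, pr$sd, min(y))
    u <- cand[which.max(ei), , drop = FALSE]
    X <- rbind(X, u)
    y <- c(y, fn(to_par(as.vector(u))))
  }
  pars <- t(t(X) * (upper - lower) + lower)
  colnames(pars) <- paste0("par", seq_len(d))
  best <- which.min(y)
  list(
    par = pars[best, ], value = y[best],
    history = dplyr::bind_cols(
      tibble(eval = seq_along(y), value = y),
      as_tibble(pars)
    )
  )
}
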
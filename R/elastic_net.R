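## In-repo penalized linear regression: standardization, regularization
## path, cyclic coordinate descent (compiled), and stratified K-fold
## cross-validation. The objective is the scikit-learn/glmnet convention
##   (1/2n) ||y - b0 - X b||^2 + lambda (l1_ratio ||b||_1 + (1-l1_ratio)/2 ||b||_2^2)
## with features standardized internally (population sd) and the fitted
## model reported on the original feature scale.

standardize_xy <- function(X, y) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)  # population sd so (1/n) xs'xs = 1
  active <- sdv > 0
  Xs <- sweep(X[, active, drop = FALSE], 2, mu[active], "-")
  Xs <- sweep(Xs, 2, sdv[active], "/")
  list(Xs = Xs, y_c = y - mean(y), y_mean = mean(y),
       mu = mu, sd = sdv, active = active, n = n)
}

#' Regularization path for the elastic net
#'
#' Geometric grid of `n_lambda` penalties from `lambda_max` (the smallest
#' penalty at which every coefficient is zero) down to `eps * lambda_max`,
#' with `lambda_max = max_j |<x_j, y_c>| / (n * l1_ratio)` computed on the
#' standardized design and centered response.
#'
#' @param X numeric feature matrix (raw scale; standardized internally).
#' @param y numeric response.
#' @param l1_ratio elastic-net mixing parameter in (0, 1]; the pure-ridge
#'   path (`l1_ratio = 0`) is undefined and errors.
#' @param n_lambda number of grid points (default 100).
#' @param eps ratio of smallest to largest lambda (default 1e-3).
#' @return numeric vector of strictly decreasing lambdas.
#' @export
lambda_path <- function(X, y, l1_ratio = 0.5, n_lambda = 100, eps = 1e-3) {
  if (l1_ratio <= 0)
    stop("lambda path undefined for l1_ratio = 0; supply lambda explicitly")
  st <- standardize_xy(as.matrix(X), y)
  if (!any(st$active)) stop("all features have zero variance")
  lambda_max <- max(abs(crossprod(st$Xs, st$y_c))) / (st$n * l1_ratio)
  if (lambda_max <= 0)
    stop("degenerate path: response is orthogonal to every feature")
  exp(seq(log(lambda_max), log(eps * lambda_max), length.out = n_lambda))
}

#' Fit an elastic-net linear model by cyclic coordinate descent
#'
#' Solves the elastic-net problem at a single penalty by cyclic coordinate
#' descent with soft-thresholding updates (deterministic coordinate order).
#' Zero-variance features receive coefficient 0 with a warning. Coefficients
#' and intercept are returned on the original feature scale;
#' standardized-scale coefficients are kept for warm starts.
#'
#' @inheritParams lambda_path
#' @param lambda penalty strength, >= 0.
#' @param tol convergence tolerance on the largest absolute standardized
#'   coefficient update per sweep (default 1e-6).
#' @param max_iter maximum number of full sweeps (default 10000).
#' @param warm_start optional standardized-scale coefficient vector (e.g.
#'   `fit$beta_std` from a fit at a nearby lambda).
#' @return an `ElasticNetFit`: coefficients (original scale), intercept,
#'   lambda, l1_ratio, iteration count, convergence flag, standardization
#'   constants and the per-sweep objective trace.
#' @export
fit_elastic_net <- function(X, y, lambda, l1_ratio = 0.5, tol = 1e-6,
                            max_iter = 10000L, warm_start = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in X or y")
  stopifnot(nrow(X) == length(y), lambda >= 0, l1_ratio >= 0, l1_ratio <= 1)
  st <- standardize_xy(X, y)
  if (!all(st$active))
    warning(sum(!st$active), " zero-variance feature(s) assigned coefficient 0")
  p_act <- ncol(st$Xs)
  b0 <- if (is.null(warm_start)) numeric(p_act) else {
    stopifnot(length(warm_start) == ncol(X))
    warm_start[st$active]
  }
  res <- .cd_enet(st$Xs, st$y_c, b0, lambda, l1_ratio, tol, as.integer(max_iter))
  if (!res$converged)
    warning("coordinate descent did not converge in ", max_iter, " sweeps")
  beta_std <- numeric(ncol(X))
  beta_std[st$active] <- res$beta
  coefficients <- numeric(ncol(X))
  coefficients[st$active] <- res$beta / st$sd[st$active]
  intercept <- st$y_mean - sum(coefficients * st$mu)
  names(coefficients) <- colnames(X)
  structure(list(coefficients = coefficients, intercept = intercept,
                 lambda = lambda, l1_ratio = l1_ratio,
                 n_iterations = res$n_iterations, converged = res$converged,
                 standardization = list(mean = st$mu, sd = st$sd),
                 beta_std = beta_std,
                 objective_trace = res$objective_trace),
            class = "ElasticNetFit")
}

#' @export
print.ElasticNetFit <- function(x, ...) {
  cat(sprintf("<ElasticNetFit> lambda=%.4g l1_ratio=%.2f: %d/%d nonzero, %s after %d sweeps\n",
              x$lambda, x$l1_ratio, sum(x$coefficients != 0),
              length(x$coefficients),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' @param object an `ElasticNetFit`.
#' @param newdata feature matrix on the original scale.
#' @param ... unused.
#' @rdname fit_elastic_net
#' @export
predict.ElasticNetFit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients) + object$intercept
}

## Round-robin fold assignment within each stratum after a seeded shuffle:
## fold sizes within a stratum differ by at most one, and a stratum smaller
## than n_folds lands one-per-fold.
make_stratified_folds <- function(strata, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(strata))
  for (g in unique(strata)) {
    idx <- which(strata == g)
    if (length(idx) < n_folds)
      warning("stratum '", g, "' has fewer members (", length(idx),
              ") than folds; spread one per fold")
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Stratified K-fold cross-validation over a lambda path
#'
#' Folds are stratified by `strata` (one seeded shuffle, round-robin
#' assignment). For each fold the model is refit along the descending lambda
#' grid with warm starts and validation mean squared error is recorded;
#' `best_lambda` minimizes the mean validation MSE (`selection = "1se"`
#' picks the largest lambda within one standard error of the minimum).
#'
#' @inheritParams fit_elastic_net
#' @param strata stratification labels, one per row of `X`.
#' @param n_folds number of folds (default 10).
#' @param lambda optional lambda grid (descending); computed by
#'   [lambda_path()] from the full data when `NULL`.
#' @param seed integer seed controlling fold assignment.
#' @param selection `"min"` (default) or `"1se"`.
#' @param n_lambda,eps passed to [lambda_path()] when `lambda` is `NULL`.
#' @return a `CVResult`: lambda grid, per-lambda mean and standard error of
#'   validation MSE, `best_lambda` and the fold assignment.
#' @export
cross_validate <- function(X, y, strata, n_folds = 10L, l1_ratio = 0.5,
                           lambda = NULL, seed = 1L,
                           selection = c("min", "1se"),
                           n_lambda = 100, eps = 1e-3, tol = 1e-6,
                           max_iter = 10000L) {
  selection <- match.arg(selection)
  X <- as.matrix(X)
  stopifnot(n_folds >= 2, length(strata) == nrow(X))
  if (is.null(lambda)) lambda <- lambda_path(X, y, l1_ratio, n_lambda, eps)
  stopifnot(all(diff(lambda) < 0))
  fold <- make_stratified_folds(strata, n_folds, seed)
  mse <- matrix(NA_real_, n_folds, length(lambda))
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    if (!any(!tr) || !any(tr)) next
    warm <- NULL
    for (li in seq_along(lambda)) {
      fit <- fit_elastic_net(X[tr, , drop = FALSE], y[tr], lambda[li],
                             l1_ratio, tol, max_iter, warm_start = warm)
      warm <- fit$beta_std
      pred <- predict(fit, X[!tr, , drop = FALSE])
      mse[k, li] <- mean((y[!tr] - pred)^2)
    }
  }
  mean_mse <- colMeans(mse, na.rm = TRUE)
  se_mse <- apply(mse, 2, function(v) sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  i_min <- which.min(mean_mse)
  best <- if (selection == "min") lambda[i_min] else {
    ok <- which(mean_mse <= mean_mse[i_min] + se_mse[i_min])
    lambda[min(ok)]  # grid is descending: smallest index = largest lambda
  }
  structure(list(lambda_grid = lambda, mean_mse = mean_mse, se_mse = se_mse,
                 best_lambda = best, fold = fold, n_folds = n_folds,
                 l1_ratio = l1_ratio, selection = selection, seed = seed),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("<CVResult> %d-fold, %d lambdas in [%.3g, %.3g]; best_lambda=%.4g (%s)\n",
              x$n_folds, length(x$lambda_grid), min(x$lambda_grid),
              max(x$lambda_grid), x$best_lambda, x$selection))
  invisible(x)
}
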
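## The statistical battery for comparing clocks, testing group differences,
## and detecting intervention effects. All p-values are two-tailed unless
## stated otherwise.

new_test_result <- function(test_name, statistic, p_value, n, effect = NULL,
                            method = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n = n, effect = effect, method = method),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("<TestResult> %s: statistic=%.6g, p=%.4g (n=%s)%s\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              if (!is.null(x$method)) paste0(" [", x$method, "]") else ""))
  invisible(x)
}

## Exact null distribution of the group-a rank sum W under the permutation
## null, ties handled through midranks. Doubled midranks are integers, so
## the distribution is computed by a subset-sum dynamic program over
## (group size, doubled rank sum): O(n * n_a * max_sum) — trivial for the
## exact regime (both groups <= ~12).
rank_sum_distribution <- function(ranks2, n_a) {
  max_sum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n_a)])
  ## f[k+1, s+1] = number of size-k subsets with doubled rank sum s
  f <- matrix(0, n_a + 1, max_sum + 1)
  f[1, 1] <- 1
  for (r in ranks2) {
    kmax <- n_a
    for (k in kmax:1) {
      nz <- which(f[k, ] > 0)
      nz <- nz[nz - 1 + r <= max_sum]
      if (length(nz)) f[k + 1, nz + r] <- f[k + 1, nz + r] + f[k, nz]
    }
  }
  f[n_a + 1, ]  # counts indexed by doubled rank sum s = index - 1
}

#' Mann-Whitney U test (exact or tie-corrected normal approximation)
#'
#' Two-sample, two-tailed rank test. In exact mode the full permutation null
#' of the rank sum is computed (ties handled through midranks), giving
#' `p = min(1, 2 * min(P(W <= w), P(W >= w)))`. In normal-approximation mode
#' the U statistic is compared to its tie-corrected normal null with
#' continuity correction. `"auto"` uses the exact mode when both groups have
#' at most `exact_limit` observations.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param exact_limit group-size threshold for auto mode (default 12).
#' @return a `TestResult` with the U statistic for group `a`.
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx"),
                           exact_limit = 12L) {
  mode <- match.arg(mode)
  stopifnot(length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  u <- w - n_a * (n_a + 1) / 2
  if (mode == "auto")
    mode <- if (n_a <= exact_limit && n_b <= exact_limit) "exact"
            else "normal_approx"
  if (length(unique(c(a, b))) == 1) {
    warning("all values tied across both groups; p = 1")
    return(new_test_result("mann_whitney_u", u, 1, c(n_a, n_b),
                           method = mode))
  }
  if (mode == "exact") {
    r2 <- as.integer(round(2 * r))
    counts <- rank_sum_distribution(r2, n_a)
    total <- sum(counts)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n_a * n_b / 2
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      warning("zero variance under ties; p = 1")
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)  # continuity correction
      p <- 2 * pnorm(max(z, 0), lower.tail = FALSE)
      p <- min(1, p)
    }
  }
  new_test_result("mann_whitney_u", u, p, c(n_a, n_b), method = mode)
}

#' Pairwise comparison of clock errors on shared samples
#'
#' Given per-clock age predictions on the same samples, computes each
#' clock's mean absolute error and all pairwise two-tailed Mann-Whitney U
#' tests on the per-sample absolute errors (unadjusted, with an optional
#' Benjamini-Hochberg column).
#'
#' @param predictions named list: one numeric vector of predicted ages
#'   (days) per clock, all aligned to `chronological`.
#' @param chronological chronological ages in days.
#' @param bh also report Benjamini-Hochberg adjusted p-values.
#' @param mwu_mode passed to [mann_whitney_u()].
#' @return list with `mae` (named vector), `abs_errors` (samples x clocks
#'   matrix), and `pairwise` (data.frame clock_a, clock_b, p_value[, p_bh]).
#' @export
compare_clock_errors <- function(predictions, chronological, bh = FALSE,
                                 mwu_mode = "auto") {
  stopifnot(is.list(predictions), length(predictions) >= 2)
  n <- length(chronological)
  if (n < 2) stop("need at least 2 shared valid samples")
  err <- vapply(predictions, function(p) {
    stopifnot(length(p) == n)
    abs(p - chronological)
  }, numeric(n))
  if (is.null(dim(err))) err <- matrix(err, nrow = n)  # n == 1 guard
  mae <- colMeans(err)
  combs <- utils::combn(names(predictions), 2)
  pw <- data.frame(clock_a = combs[1, ], clock_b = combs[2, ],
                   p_value = apply(combs, 2, function(cc)
                     mann_whitney_u(err[, cc[1]], err[, cc[2]],
                                    mode = mwu_mode)$p_value))
  if (bh) pw$p_bh <- stats::p.adjust(pw$p_value, method = "BH")
  list(mae = mae, abs_errors = err, pairwise = pw)
}

#' Residual-slope diagnostic for systematic clock bias
#'
#' Ordinary least squares of the residual (predicted minus chronological
#' age) on chronological age, with the t-test of the slope against zero. A
#' clock without systematic age-dependent bias has residual slope
#' indistinguishable from 0 (equivalently, slope 1 in the regression of
#' predicted on chronological age).
#'
#' @param predicted predicted ages (days).
#' @param chronological chronological ages (days), at least 2 distinct.
#' @return list with `slope`, `intercept`, `p_slope_vs_0`, `n`.
#' @export
residual_slope_test <- function(predicted, chronological) {
  stopifnot(length(predicted) == length(chronological),
            length(predicted) >= 3)
  if (length(unique(chronological)) < 2)
    stop("chronological ages are constant; slope undefined")
  fit <- lm(I(predicted - chronological) ~ chronological)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p_slope_vs_0 = unname(sm[2, 4]), n = length(predicted))
}

#' Compare age-regression slope and intercept between two groups
#'
#' Fits a combined OLS of predicted age on chronological age with a group
#' indicator. The slope-difference p-value comes from the group-by-age
#' interaction term; the intercept-difference p-value comes from the group
#' term in the additive (no-interaction) model. This is the standard test
#' for, e.g., sex-dependent age acceleration.
#'
#' @param ages1,predictions1 chronological and predicted ages, group 1.
#' @param ages2,predictions2 chronological and predicted ages, group 2.
#' @return list with `slope_difference`, `p_slope_difference`,
#'   `intercept_difference`, `p_intercept_difference`.
#' @export
group_regression_comparison <- function(ages1, predictions1,
                                        ages2, predictions2) {
  stopifnot(length(ages1) == length(predictions1),
            length(ages2) == length(predictions2),
            length(ages1) >= 3, length(ages2) >= 3)
  if (length(unique(ages1)) < 2 || length(unique(ages2)) < 2)
    stop("collinear design: each group needs >= 2 distinct ages")
  age <- c(ages1, ages2)
  pred <- c(predictions1, predictions2)
  grp <- factor(rep(c("g1", "g2"), c(length(ages1), length(ages2))))
  full <- lm(pred ~ age * grp)
  addv <- lm(pred ~ age + grp)
  cf <- summary(full)$coefficients
  ca <- summary(addv)$coefficients
  int_row <- grep(":", rownames(cf))
  grp_row <- grep("^grp", rownames(ca))
  list(slope_difference = unname(coef(full)[grep(":", names(coef(full)))]),
       p_slope_difference = unname(cf[int_row, 4]),
       intercept_difference = unname(coef(addv)[grp_row]),
       p_intercept_difference = unname(ca[grp_row, 4]))
}

#' Test an intervention effect on epigenetic age acceleration
#'
#' Two-tailed Mann-Whitney U test on the delta-age (DNAm age minus
#' chronological age) distributions of control and treated groups. The
#' effect direction is the sign of the treated-minus-control median shift;
#' lifespan-extending interventions are expected to shift delta-age
#' negative.
#'
#' @param control,treated numeric delta-age vectors, or data.frames from
#'   [predict_age()] with a `delta_age_days` column.
#' @param mode passed to [mann_whitney_u()].
#' @return a `TestResult` whose `effect` holds the direction (-1/0/1) and
#'   the median shift in days.
#' @export
intervention_effect <- function(control, treated, mode = "auto") {
  get_delta <- function(x)
    if (is.data.frame(x)) x$delta_age_days else as.numeric(x)
  dc <- get_delta(control); dt_ <- get_delta(treated)
  if (!length(dc) || !length(dt_)) stop("empty group")
  if (anyNA(dc) || anyNA(dt_)) stop("delta-age undefined for some samples")
  res <- mann_whitney_u(dt_, dc, mode = mode)
  shift <- median(dt_) - median(dc)
  new_test_result("intervention_effect", res$statistic, res$p_value,
                  c(length(dc), length(dt_)),
                  effect = list(direction = sign(shift),
                                median_shift_days = shift),
                  method = res$method)
}

#' Correlation matrices of clock predictions and of delta-ages
#'
#' Pearson correlation between clocks computed twice: on the DNAm ages
#' themselves and on the delta-ages (predicted minus chronological), which
#' removes the shared chronological trend.
#'
#' @param predictions named list of predicted-age vectors on shared samples.
#' @param chronological chronological ages (days).
#' @return list of two symmetric unit-diagonal matrices, `age_r` and
#'   `delta_r`; zero-variance vectors give `NA` entries with a warning.
#' @export
clock_correlations <- function(predictions, chronological) {
  stopifnot(length(chronological) >= 3)
  P <- vapply(predictions, identity, numeric(length(chronological)))
  D <- P - chronological
  safe_cor <- function(M) {
    v <- apply(M, 2, var)
    if (any(v == 0))
      warning("zero-variance prediction vector; correlation set to NA")
    r <- suppressWarnings(cor(M))
    r[cbind(seq_len(ncol(M)), seq_len(ncol(M)))] <- 1
    r
  }
  list(age_r = safe_cor(P), delta_r = safe_cor(D))
}

## Bartlett's test of equal variances, closed form:
##   X^2 = [(N-k) ln Sp^2 - sum (n_i-1) ln s_i^2] / C,
##   C   = 1 + (sum 1/(n_i-1) - 1/(N-k)) / (3(k-1)),
## compared to chi-square with k-1 df.
bartlett_statistic <- function(groups) {
  k <- length(groups)
  n_i <- vapply(groups, length, integer(1))
  if (any(n_i < 2)) stop("Bartlett's test needs >= 2 observations per group")
  s2 <- vapply(groups, var, numeric(1))
  N <- sum(n_i)
  sp2 <- sum((n_i - 1) * s2) / (N - k)
  C <- 1 + (sum(1 / (n_i - 1)) - 1 / (N - k)) / (3 * (k - 1))
  stat <- ((N - k) * log(sp2) - sum((n_i - 1) * log(s2))) / C
  list(statistic = stat, df = k - 1,
       p_value = pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Weight-distribution symmetry and variance-homogeneity tests
#'
#' For each clock, tests zero-symmetry of the weight distribution with a
#' two-tailed Mann-Whitney U comparing positive weights against absolute
#' values of negative weights; across clocks, tests homogeneity of weight
#' variances with Bartlett's test.
#'
#' @param clocks named list of `ClockDefinition` objects (>= 2 for
#'   Bartlett).
#' @return list with `symmetry` (named list of `TestResult`, `NA` p-value
#'   with a warning for one-signed clocks) and `variance_homogeneity`
#'   (a `TestResult` over all clocks' weight vectors).
#' @export
weight_distribution_tests <- function(clocks) {
  if (is.null(names(clocks)))
    names(clocks) <- vapply(clocks, function(cl) cl$name, character(1))
  symmetry <- lapply(clocks, function(cl) {
    w <- cl$sites$weight
    pos <- w[w > 0]; neg <- -w[w < 0]
    if (length(pos) < 2 || length(neg) < 2) {
      warning("clock '", cl$name,
              "' has a one-signed weight vector; symmetry test NA")
      return(new_test_result("weight_symmetry", NA_real_, NA_real_,
                             c(length(pos), length(neg))))
    }
    res <- mann_whitney_u(pos, neg)
    new_test_result("weight_symmetry", res$statistic, res$p_value, res$n,
                    method = res$method)
  })
  homo <- NULL
  if (length(clocks) >= 2) {
    bt <- bartlett_statistic(lapply(clocks, function(cl) cl$sites$weight))
    homo <- new_test_result("bartlett_variance_homogeneity", bt$statistic,
                            bt$p_value,
                            vapply(clocks, function(cl) nrow(cl$sites),
                                   integer(1)))
  }
  list(symmetry = symmetry, variance_homogeneity = homo)
}
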
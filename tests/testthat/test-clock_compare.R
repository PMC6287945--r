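test_that("exact MWU matches full enumeration, including the canonical case", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  # identical multisets -> p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3), mode = "exact")$p_value,
               1)
  set.seed(17)
  for (rep in 1:20) {
    n_a <- sample(2:7, 1); n_b <- sample(2:7, 1)
    vals <- if (rep %% 2) rnorm(n_a + n_b) else sample(1:4, n_a + n_b, TRUE)
    a <- vals[seq_len(n_a)]; b <- vals[-seq_len(n_a)]
    if (length(unique(vals)) == 1) next
    expect_equal(mann_whitney_u(a, b, mode = "exact")$p_value,
                 mwu_enum_oracle(a, b), tolerance = 1e-12,
                 info = paste("rep", rep))
    # swap symmetry
    expect_equal(mann_whitney_u(a, b, mode = "exact")$p_value,
                 mann_whitney_u(b, a, mode = "exact")$p_value)
  }
})

test_that("U statistic identity and degenerate ties", {
  set.seed(23)
  for (rep in 1:10) {
    a <- sample(1:5, sample(2:8, 1), TRUE)
    b <- sample(1:5, sample(2:8, 1), TRUE)
    ua <- mann_whitney_u(a, b)$statistic
    ub <- mann_whitney_u(b, a)$statistic
    expect_equal(ua + ub, length(a) * length(b))
  }
  expect_warning(r <- mann_whitney_u(rep(2, 4), rep(2, 5)), "tied")
  expect_equal(r$p_value, 1)
})

test_that("normal approximation is close to exact for moderate n", {
  set.seed(29)
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(8, 0.8)
    pe <- mann_whitney_u(a, b, mode = "exact")$p_value
    pn <- mann_whitney_u(a, b, mode = "normal_approx")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("compare_clock_errors: MAE table and pairwise exact tests", {
  chron <- c(100, 200, 300, 400, 150, 250, 350, 450)
  pa <- chron + 1          # errors all 1 day
  pb <- chron + 100        # errors all 100 days
  cmp <- compare_clock_errors(list(A = pa, B = pb), chron)
  expect_equal(unname(cmp$mae), c(1, 100))
  expect_equal(cmp$pairwise$p_value,
               mwu_enum_oracle(abs(pa - chron), abs(pb - chron)))
  expect_equal(unname(colMeans(cmp$abs_errors)), unname(cmp$mae))
  # identical predictions -> p = 1
  same <- suppressWarnings(compare_clock_errors(list(A = pa, B = pa), chron))
  expect_equal(same$pairwise$p_value, 1)
  expect_error(compare_clock_errors(list(A = 1, B = 2), chronological = 5),
               "2 shared")
  with_bh <- compare_clock_errors(list(A = pa, B = pb, C = chron + 10),
                                  chron, bh = TRUE)
  expect_true("p_bh" %in% names(with_bh$pairwise))
})

test_that("residual slope test: exact algebraic cases", {
  age <- c(50, 150, 250, 350, 450)
  # perfect predictions: slope exactly 0
  expect_equal(residual_slope_test(age, age)$slope, 0)
  # constant predictions: slope exactly -1
  r <- suppressWarnings(residual_slope_test(rep(200, 5), age))
  expect_equal(r$slope, -1, tolerance = 1e-12)
  # compressed predictions: slope 0.5 - 1 = -0.5
  r2 <- suppressWarnings(residual_slope_test(0.5 * age + 30, age))
  expect_equal(r2$slope, -0.5, tolerance = 1e-12)
  expect_error(residual_slope_test(c(1, 2, 3), c(5, 5, 5)), "constant")
})

test_that("residual slope equals (prediction-vs-age slope) - 1 on any input", {
  set.seed(37)
  for (rep in 1:5) {
    age <- runif(20, 10, 1000)
    pred <- 0.7 * age + rnorm(20, 0, 40)
    rs <- residual_slope_test(pred, age)$slope
    ols <- unname(coef(lm(pred ~ age))[2])
    expect_equal(rs, ols - 1, tolerance = 1e-10)
  }
})

test_that("group regression comparison: affine and closed-form cases", {
  age <- c(60, 120, 180, 240, 300, 360)
  pred <- age + c(3, -2, 4, -1, 0, 2)
  same <- group_regression_comparison(age, pred, age, pred)
  expect_equal(same$slope_difference, 0, tolerance = 1e-10)
  expect_equal(same$intercept_difference, 0, tolerance = 1e-10)
  shift <- group_regression_comparison(age, pred, age, pred + 50)
  expect_equal(shift$intercept_difference, 50, tolerance = 1e-10)
  expect_equal(shift$slope_difference, 0, tolerance = 1e-10)
  steep <- suppressWarnings(
    group_regression_comparison(age, 1.0 * age, age, 1.5 * age))
  expect_equal(steep$slope_difference, 0.5, tolerance = 1e-10)
  expect_error(group_regression_comparison(rep(100, 3), 1:3, age[1:3], 1:3),
               "collinear")
})

test_that("group regression p-values are large for noisy same-slope groups", {
  set.seed(41)
  age1 <- runif(30, 50, 1000); age2 <- runif(30, 50, 1000)
  g <- group_regression_comparison(age1, age1 + rnorm(30, 0, 50),
                                   age2, age2 + rnorm(30, 0, 50))
  expect_gt(g$p_slope_difference, 0.05)
  expect_gt(g$p_intercept_difference, 0.05)
})

test_that("intervention effect on delta-age", {
  r <- intervention_effect(control = c(-5, 0, 5),
                           treated = c(-65, -60, -55))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$effect$direction, -1)
  same <- intervention_effect(c(-5, 0, 5), c(-5, 0, 5))
  expect_equal(same$p_value, 1)
  expect_equal(same$effect$direction, 0)
  expect_error(intervention_effect(numeric(0), 1:3), "empty")
  # data.frame input with the prediction-table column
  ctrl <- data.frame(delta_age_days = c(-5, 0, 5))
  trt <- data.frame(delta_age_days = c(-65, -60, -55))
  expect_equal(intervention_effect(ctrl, trt)$p_value, 0.1)
  # single extreme treated value against a larger control group
  a <- 1:9
  expect_equal(intervention_effect(a, 100)$p_value, mwu_enum_oracle(100, a))
})

test_that("clock correlations on ages and on delta-ages differ as constructed", {
  chron <- seq(10, 200, by = 10)
  r1 <- rep(c(30, -30), 10)
  r2 <- rep(c(30, 30, -30, -30), 5)
  stopifnot(abs(cor(r1, r2)) < 1e-12)
  res <- clock_correlations(list(A = chron + r1, B = chron + r2), chron)
  expect_equal(diag(res$age_r), c(A = 1, B = 1))
  expect_gt(res$age_r["A", "B"], 0.7)
  expect_lt(abs(res$delta_r["A", "B"]), 1e-9)
  ident <- suppressWarnings(clock_correlations(list(A = chron, B = chron), chron))
  expect_equal(ident$age_r["A", "B"], 1)
  neg <- suppressWarnings(clock_correlations(list(A = chron, B = -chron), chron))
  expect_equal(neg$age_r["A", "B"], -1)
  # warns once per matrix (ages and delta-ages)
  expect_warning(expect_warning(
    z <- clock_correlations(list(A = chron, B = rep(100, 20)), chron),
    "zero-variance"), "zero-variance")
  expect_true(is.na(z$age_r["A", "B"]))
})

test_that("weight symmetry and Bartlett homogeneity", {
  sym <- toy_clock(c(-2, -1, 1, 2))
  res <- weight_distribution_tests(list(S = sym))
  expect_equal(res$symmetry$S$p_value, 1)
  # identical weight multisets -> Bartlett statistic 0, p 1
  two <- weight_distribution_tests(list(A = sym, B = toy_clock(c(-2, -1, 1, 2),
                                                               pos = 1:4 * 7L)))
  expect_equal(two$variance_homogeneity$statistic, 0)
  expect_equal(two$variance_homogeneity$p_value, 1)
  # one-signed clock: NA with warning
  expect_warning(res1 <- weight_distribution_tests(
    list(P = toy_clock(c(1, 2, 3)))), "one-signed")
  expect_true(is.na(res1$symmetry$P$p_value))
})

test_that("Bartlett implementation matches stats::bartlett.test", {
  set.seed(43)
  groups <- list(rnorm(20, sd = 1), rnorm(20, sd = 1), rnorm(20, sd = 10))
  ours <- rrbsclock:::bartlett_statistic(groups)
  ref <- stats::bartlett.test(groups)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_lt(ours$p_value, 1e-10)
  # through the clock-facing interface
  clocks <- lapply(seq_along(groups), function(i)
    toy_clock(groups[[i]], pos = seq_len(20) * 13L + i))
  names(clocks) <- c("a", "b", "c")
  wt <- weight_distribution_tests(clocks)
  expect_equal(wt$variance_homogeneity$statistic, ours$statistic)
})
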
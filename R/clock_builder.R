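## Orchestration of the full clock-construction recipe: stratified split,
## regularization path, tissue-stratified cross-validation, final fit, and
## the resampling robustness study (many clocks, varying splits).

#' Training configuration for [train_clock()]
#'
#' @param test_fraction held-out fraction (default 0.2).
#' @param n_folds cross-validation folds (default 10).
#' @param l1_ratio elastic-net mixing parameter (default 1, pure L1). With a
#'   response in days the ridge component of a mixed penalty scales with the
#'   response variance and crushes sparse solutions (the cross-validation
#'   curve becomes monotone and selects dense, mostly-noise models); pure L1
#'   gives an interior CV minimum and genuine site selection. See the
#'   methods vignette.
#' @param seed integer seed driving split and fold assignment.
#' @param response_scale `"linear_days"` trains on age in days and yields an
#'   identity-transform clock; `"log_days"` trains on log(age) and yields an
#'   `exp_linear(a=1, b=0)` clock (the convention of young-age-tuned
#'   clocks).
#' @param n_lambda,lambda_min_ratio lambda grid shape (see [lambda_path()]).
#' @param selection CV selection rule, `"min"` or `"1se"`.
#' @param min_site_fraction coverage-validity threshold stored on the clock.
#' @return a named list of training settings.
#' @export
train_config <- function(test_fraction = 0.2, n_folds = 10L, l1_ratio = 1,
                         seed = 1L,
                         response_scale = c("linear_days", "log_days"),
                         n_lambda = 100L, lambda_min_ratio = 1e-3,
                         selection = "min", min_site_fraction = 0.9) {
  list(test_fraction = test_fraction, n_folds = n_folds, l1_ratio = l1_ratio,
       seed = seed, response_scale = match.arg(response_scale),
       n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
       selection = selection, min_site_fraction = min_site_fraction)
}

#' Train a methylation clock
#'
#' Full recipe on a fully-observed methylation matrix: tissue-stratified
#' 80/20 split, lambda path on the training split, tissue-stratified K-fold
#' cross-validation with warm starts, final elastic-net fit on the whole
#' training split at the selected lambda, and extraction of the
#' nonzero-coefficient CpG sites as a `ClockDefinition` (with per-site
#' training means stored for later imputation).
#'
#' @param matrix a fully-observed `MethylationMatrix` (run [common_sites()]
#'   first); metadata is taken from `matrix$samples`.
#' @param config list from [train_config()].
#' @param name clock name (default "clock").
#' @return list with `clock` (a `ClockDefinition`) and `report` (a
#'   `TrainingReport`: n per set, MAE and R-squared per set, per-tissue MAE,
#'   chosen lambda, number of sites, seed, and the held-out predictions).
#' @export
train_clock <- function(matrix, config = train_config(), name = "clock") {
  md <- matrix$samples
  if (any(!matrix$mask))
    stop("matrix must be fully observed; apply common_sites() first")
  if (length(unique(md$age_days)) < 2)
    stop("degenerate response: all samples have the same age")
  split <- stratified_split(md, config$test_fraction, seed = config$seed)
  tr <- md$sample_id %in% split$train
  X <- matrix$pct
  y_raw <- md$age_days
  y <- if (config$response_scale == "log_days") log(y_raw) else y_raw

  grid <- lambda_path(X[tr, , drop = FALSE], y[tr], config$l1_ratio,
                      config$n_lambda, config$lambda_min_ratio)
  cv <- cross_validate(X[tr, , drop = FALSE], y[tr], strata = md$tissue[tr],
                       n_folds = config$n_folds, l1_ratio = config$l1_ratio,
                       lambda = grid, seed = config$seed,
                       selection = config$selection)
  ## warm start from the path position just above best_lambda
  fit <- fit_elastic_net(X[tr, , drop = FALSE], y[tr], cv$best_lambda,
                         config$l1_ratio)
  nz <- which(fit$coefficients != 0)
  if (!length(nz))
    stop("selected lambda produced an empty clock (no nonzero coefficients)")
  clock <- clock_definition(
    name = name,
    sites = data.frame(matrix$sites[nz, c("chrom", "pos")],
                       weight = unname(fit$coefficients[nz]),
                       train_mean = unname(colMeans(X[tr, nz, drop = FALSE]))),
    intercept = fit$intercept,
    transform = if (config$response_scale == "log_days")
      transform_spec("exp_linear", a = 1, b = 0)
    else transform_spec("identity"),
    min_site_fraction = config$min_site_fraction)

  pred <- predict_age(clock, matrix)
  train_metrics <- evaluate_clock(clock, matrix, subset = split$train,
                                  predictions = pred)
  test_metrics <- if (length(split$test))
    evaluate_clock(clock, matrix, subset = split$test, predictions = pred)
  else NULL
  report <- structure(list(
    clock_name = name, n_train = sum(tr), n_test = length(split$test),
    train = train_metrics, test = test_metrics,
    lambda = cv$best_lambda, l1_ratio = config$l1_ratio,
    n_nonzero_sites = nrow(clock$sites), seed = config$seed,
    response_scale = config$response_scale,
    split = split, cv = cv,
    predictions = pred), class = "TrainingReport")
  list(clock = clock, report = report)
}

#' @export
print.TrainingReport <- function(x, ...) {
  cat(sprintf("<TrainingReport> %s: %d sites (lambda=%.4g)\n", x$clock_name,
              x$n_nonzero_sites, x$lambda))
  cat(sprintf("  train (n=%d): MAE %.2f days, R2 %.3f\n", x$n_train,
              x$train$mae_days, x$train$r_squared))
  if (!is.null(x$test))
    cat(sprintf("  test  (n=%d): MAE %.2f days, R2 %.3f\n", x$n_test,
                x$test$mae_days, x$test$r_squared))
  invisible(x)
}

#' Evaluate a clock on (a subset of) a cohort
#'
#' MAE is `mean(|predicted - chronological|)` in days; R-squared is
#' `1 - SS_res / SS_tot` of predicted versus chronological age.
#'
#' @param clock a `ClockDefinition`.
#' @param matrix a `MethylationMatrix` with `age_days` in its metadata.
#' @param subset sample ids to evaluate on (default all).
#' @param predictions optional precomputed [predict_age()] output for the
#'   whole matrix (avoids recomputation).
#' @return list with `mae_days`, `r_squared`, `per_tissue_mae`, `n`.
#' @export
evaluate_clock <- function(clock, matrix, subset = NULL, predictions = NULL) {
  md <- matrix$samples
  if (is.null(subset)) subset <- md$sample_id
  if (!length(subset)) stop("empty evaluation subset")
  if (is.null(predictions)) predictions <- predict_age(clock, matrix)
  i <- match(subset, predictions$sample_id)
  if (anyNA(i)) stop("subset sample(s) without predictions: ",
                     paste(subset[is.na(i)], collapse = ", "))
  pred <- predictions$predicted_age_days[i]
  age <- md$age_days[match(subset, md$sample_id)]
  abs_err <- abs(pred - age)
  ss_res <- sum((age - pred)^2)
  ss_tot <- sum((age - mean(age))^2)
  tissue <- md$tissue[match(subset, md$sample_id)]
  list(mae_days = mean(abs_err),
       r_squared = 1 - ss_res / ss_tot,
       per_tissue_mae = vapply(split(abs_err, tissue), mean, numeric(1)),
       n = length(subset))
}

#' Resampling robustness study: many clocks, varying splits
#'
#' Repeats the full [train_clock()] recipe `n_resamples` times with the same
#' configuration but a different seed per run (`base_seed + i`), so the
#' train/test partition varies while the procedure stays fixed. Records, for
#' every CpG site ever selected, in how many of the resampled clocks it
#' appears.
#'
#' @param matrix fully-observed `MethylationMatrix`.
#' @param n_resamples number of resampled clocks (default 100).
#' @param base_seed base seed; run i uses `base_seed + i`.
#' @param config training configuration shared by all runs (its `seed` field
#'   is overridden per run).
#' @return a `RobustnessResult`: `n_resamples` (effective), `site_counts`
#'   (named integer vector over the union of selected sites), and
#'   `per_resample` (data.frame: seed, n_sites, test MAE).
#' @export
resample_clocks <- function(matrix, n_resamples = 100L, base_seed = 1L,
                            config = train_config()) {
  counts <- integer(0)
  per <- vector("list", n_resamples)
  n_ok <- 0L
  for (i in seq_len(n_resamples)) {
    cfg <- config
    cfg$seed <- base_seed + i
    res <- tryCatch(train_clock(matrix, cfg, name = paste0("resample_", i)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("resample ", i, " failed and was skipped: ",
              conditionMessage(res))
      next
    }
    n_ok <- n_ok + 1L
    keys <- site_key(res$clock$sites$chrom, res$clock$sites$pos)
    new <- setdiff(keys, names(counts))
    if (length(new)) counts[new] <- 0L
    counts[keys] <- counts[keys] + 1L
    per[[i]] <- data.frame(resample = i, seed = cfg$seed,
                           n_sites = nrow(res$clock$sites),
                           test_mae_days = if (is.null(res$report$test))
                             NA_real_ else res$report$test$mae_days)
  }
  if (n_ok == 0) stop("every resample failed")
  structure(list(n_resamples = n_ok,
                 site_counts = counts,
                 per_resample = do.call(rbind, per[!vapply(per, is.null, TRUE)])),
            class = "RobustnessResult")
}

#' @export
print.RobustnessResult <- function(x, ...) {
  cat(sprintf("<RobustnessResult> %d resamples; %d distinct sites selected (max count %d)\n",
              x$n_resamples, length(x$site_counts),
              if (length(x$site_counts)) max(x$site_counts) else 0L))
  invisible(x)
}

#' Enrichment and weight-frequency statistics for a robustness study
#'
#' Over the reference clock's sites (appearance count 0 for sites never
#' selected in a resample): (i) a two-tailed rank-sum test comparing the
#' appearance counts of a highlighted subset (e.g. sites shared with another
#' clock) against the remaining reference sites; (ii) the squared Pearson
#' correlation between absolute reference weight and appearance count, with
#' its t-test p-value.
#'
#' @param robustness a `RobustnessResult`.
#' @param reference_clock the `ClockDefinition` whose sites are analysed.
#' @param highlight_sites character site keys (or data.frame with
#'   chrom/pos), a nonempty proper subset of the reference clock's sites.
#' @return list with `enrichment` (a `TestResult`) and `weight_frequency`
#'   (list: `r_squared`, `p_value`, `n`).
#' @export
robustness_stats <- function(robustness, reference_clock, highlight_sites) {
  ref_keys <- site_key(reference_clock$sites$chrom, reference_clock$sites$pos)
  if (is.data.frame(highlight_sites))
    highlight_sites <- site_key(normalize_chrom(highlight_sites$chrom),
                                highlight_sites$pos)
  if (!all(highlight_sites %in% ref_keys))
    stop("highlight_sites must be a subset of the reference clock's sites")
  if (!length(highlight_sites) || length(highlight_sites) >= length(ref_keys))
    stop("highlight_sites must be a nonempty proper subset")
  counts <- robustness$site_counts[ref_keys]
  counts[is.na(counts)] <- 0L
  names(counts) <- ref_keys
  hi <- counts[highlight_sites]
  rest <- counts[setdiff(ref_keys, highlight_sites)]
  enrich <- mann_whitney_u(as.numeric(hi), as.numeric(rest))
  w <- abs(reference_clock$sites$weight)
  wf <- if (var(w) == 0 || var(as.numeric(counts)) == 0) {
    warning("zero variance in |weight| or appearance counts; correlation NA")
    list(r_squared = NA_real_, p_value = NA_real_, n = length(counts))
  } else {
    r <- cor(w, as.numeric(counts))
    n <- length(counts)
    p <- if (n > 2 && abs(r) < 1) {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
    } else if (abs(r) >= 1 && n > 2) 0 else NA_real_
    list(r_squared = r^2, p_value = p, n = n)
  }
  list(enrichment = enrich, weight_frequency = wf)
}
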
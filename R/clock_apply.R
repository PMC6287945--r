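## Applying a clock definition to methylation data: linear score over
## percent methylation, explicit missing-site policy, coverage accounting,
## and the score -> age transform.

#' Apply an age transform to a linear score
#'
#' `identity` returns the score; `exp_linear` returns `exp(a*score + b)`
#' (clocks trained on log age); `logistic` returns
#' `c / (1 + exp(-a*score - b))`. Exponent arguments are clipped to keep the
#' result finite, with a warning.
#'
#' @param score numeric vector of linear clock scores.
#' @param transform a `TransformSpec` from [transform_spec()].
#' @return numeric vector of ages (days).
#' @export
apply_transform <- function(score, transform) {
  transform <- validate_transform(transform)
  p <- transform$params
  switch(transform$form,
    identity = score,
    exp_linear = {
      z <- p$a * score + p$b
      if (any(z > 700)) { warning("exp_linear argument clipped to 700"); z <- pmin(z, 700) }
      exp(z)
    },
    logistic = {
      z <- -p$a * score - p$b
      if (any(z > 700)) { warning("logistic argument clipped to 700"); z <- pmin(z, 700) }
      p$c / (1 + exp(z))
    })
}

#' Predict DNA methylation age with a clock
#'
#' Computes the linear score `sum_i w_i * m_i + intercept` over the clock's
#' CpG sites (percent methylation, 0–100), applies the clock's age
#' transform, and reports coverage accounting per sample. Uncovered clock
#' sites are imputed according to `missing_policy`:
#' \describe{
#'   \item{train_mean}{stored training-set means (errors if absent)}
#'   \item{global_mean_50}{flat 50\% methylation}
#'   \item{strict}{error listing the missing sites}
#'   \item{auto}{train_mean when means are stored, else global_mean_50}
#' }
#' Predictions with clock-site coverage below the clock's
#' `min_site_fraction` are flagged `valid = FALSE` but still returned.
#'
#' @param clock a `ClockDefinition`.
#' @param x a `MethylationMatrix` or a single `SampleMethylome`.
#' @param missing_policy imputation policy (see above).
#' @param age_days optional chronological ages (taken from matrix metadata
#'   when present) used to compute `delta_age_days`.
#' @return data.frame with one row per sample: `sample_id`,
#'   `predicted_age_days`, `score`, `n_clock_sites_covered`,
#'   `fraction_covered`, `valid`, `delta_age_days`.
#' @export
predict_age <- function(clock, x,
                        missing_policy = c("auto", "train_mean",
                                           "global_mean_50", "strict"),
                        age_days = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (missing_policy == "auto")
    missing_policy <- if (all(is.finite(clock$sites$train_mean)))
      "train_mean" else "global_mean_50"
  keys <- site_key(clock$sites$chrom, clock$sites$pos)
  w <- clock$sites$weight
  if (inherits(x, "SampleMethylome")) {
    m_obs <- setNames(x$sites$pct, site_key(x$sites$chrom, x$sites$pos))
    pct <- matrix(m_obs[keys], nrow = 1,
                  dimnames = list(x$sample_id, keys))
    observed <- !is.na(pct)
    ids <- x$sample_id
  } else if (inherits(x, "MethylationMatrix")) {
    j <- match(keys, colnames(x$pct))
    n <- nrow(x$samples)
    pct <- matrix(NA_real_, n, length(keys),
                  dimnames = list(x$samples$sample_id, keys))
    observed <- matrix(FALSE, n, length(keys))
    hit <- !is.na(j)
    pct[, hit] <- x$pct[, j[hit], drop = FALSE]
    observed[, hit] <- x$mask[, j[hit], drop = FALSE]
    pct[!observed] <- NA_real_
    ids <- x$samples$sample_id
    if (is.null(age_days) && "age_days" %in% names(x$samples))
      age_days <- x$samples$age_days
  } else stop("x must be a MethylationMatrix or SampleMethylome")

  if (missing_policy == "strict" && any(!observed)) {
    miss <- unique(colnames(pct)[which(!observed, arr.ind = TRUE)[, 2]])
    stop("missing clock site(s) under strict policy: ",
         paste(head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10))
  }
  impute <- switch(missing_policy,
    train_mean = {
      if (!all(is.finite(clock$sites$train_mean)))
        stop("clock '", clock$name, "' stores no training means; ",
             "use missing_policy = 'global_mean_50' or 'strict'")
      clock$sites$train_mean
    },
    global_mean_50 = rep(50, length(keys)),
    strict = rep(NA_real_, length(keys)))
  for (jj in seq_along(keys)) pct[!observed[, jj], jj] <- impute[jj]

  score <- drop(pct %*% w) + clock$intercept
  n_cov <- rowSums(observed)
  frac <- n_cov / length(keys)
  data.frame(sample_id = ids,
             predicted_age_days = apply_transform(score, clock$transform),
             score = score,
             n_clock_sites_covered = as.integer(n_cov),
             fraction_covered = frac,
             valid = frac >= clock$min_site_fraction,
             delta_age_days = if (is.null(age_days)) NA_real_
                              else apply_transform(score, clock$transform) - age_days,
             row.names = NULL)
}

#' Clock-site coverage accounting
#'
#' For each sample, how many of the clock's CpG sites are observed, plus the
#' cohort median (a fully-representative cohort has median equal to the
#' clock size).
#'
#' @inheritParams predict_age
#' @return list with `per_sample` (data.frame: sample_id, n_covered,
#'   fraction) and `median_n_covered`.
#' @export
clock_coverage <- function(clock, x) {
  keys <- site_key(clock$sites$chrom, clock$sites$pos)
  if (inherits(x, "SampleMethylome")) {
    obs <- matrix(keys %in% site_key(x$sites$chrom, x$sites$pos), nrow = 1)
    ids <- x$sample_id
  } else {
    j <- match(keys, colnames(x$pct))
    obs <- matrix(FALSE, nrow(x$samples), length(keys))
    hit <- !is.na(j)
    obs[, hit] <- x$mask[, j[hit], drop = FALSE]
    ids <- x$samples$sample_id
  }
  n_cov <- rowSums(obs)
  list(per_sample = data.frame(sample_id = ids, n_covered = as.integer(n_cov),
                               fraction = n_cov / length(keys),
                               row.names = NULL),
       median_n_covered = median(n_cov))
}

#' Write age predictions as TSV
#' @param predictions data.frame from [predict_age()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  data.table::fwrite(predictions, path, sep = "\t")
  invisible(path)
}
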
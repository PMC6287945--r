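## Age-structured synthetic RRBS cohorts with the statistical structure a
## linear methylation clock assumes: a subset of CpG sites whose mean
## methylation drifts linearly with age toward intermediate levels,
## negative-binomial read depth, binomial methylated-read noise, per-cell
## dropout, and tissue/batch offsets.

#' Synthetic cohort configuration
#'
#' Defaults describe a desk-scale whole-lifespan mouse cohort: ages uniform
#' over 7–1050 days (one week to 35 months), four tissues, mean depth 30x
#' with negative-binomial overdispersion, and informative sites drifting
#' toward 50\% methylation at 0.015–0.04 percentage points per day (a
#' 15–40 point shift across the lifespan).
#'
#' @param n_samples number of samples (default 200).
#' @param n_sites number of CpG sites (default 2000).
#' @param n_informative number of truly age-informative sites (default 40).
#' @param age_range_days min/max chronological age in days.
#' @param tissues named numeric: tissue labels with methylation offset
#'   magnitudes (sd, percentage points) applied to a random site subset.
#' @param tissue_affected_fraction fraction of sites carrying tissue
#'   offsets.
#' @param drift_target_pct methylation level informative sites drift toward
#'   (default 50; must lie in \[0, 100\]).
#' @param slope_range_pct_per_day magnitude range of informative-site drift
#'   slopes.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   (mean and size).
#' @param dropout_prob marginal per-(sample, site) probability of an
#'   unobserved cell (in addition to sampled depth 0). Dropout is
#'   site-structured: a fraction `dropout_site_fraction` of sites are
#'   "variably covered" and absorb all of the dropout (per-cell rate
#'   `dropout_prob / dropout_site_fraction`, capped at 1), while the
#'   remaining sites form the stable common core characteristic of RRBS.
#' @param dropout_site_fraction fraction of sites carrying the dropout
#'   (default 0.1).
#' @param n_batches,batch_sd number of batches and sd (percentage points) of
#'   the per-batch global methylation offset.
#' @param seed integer seed; the cohort is bit-identical for a fixed seed.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_samples = 200L, n_sites = 2000L,
                             n_informative = 40L,
                             age_range_days = c(7, 1050),
                             tissues = c(blood = 0, liver = 4, lung = 4,
                                         cortex = 4),
                             tissue_affected_fraction = 0.2,
                             drift_target_pct = 50,
                             slope_range_pct_per_day = c(0.015, 0.04),
                             depth_mean = 30, depth_dispersion = 5,
                             dropout_prob = 0.05,
                             dropout_site_fraction = 0.1,
                             n_batches = 2L, batch_sd = 2,
                             seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
              n_informative = as.integer(n_informative),
              age_range_days = age_range_days, tissues = tissues,
              tissue_affected_fraction = tissue_affected_fraction,
              drift_target_pct = drift_target_pct,
              slope_range_pct_per_day = slope_range_pct_per_day,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              dropout_prob = dropout_prob,
              dropout_site_fraction = dropout_site_fraction,
              n_batches = as.integer(n_batches),
              batch_sd = batch_sd, seed = as.integer(seed))
  if (cfg$n_informative > cfg$n_sites)
    stop("n_informative must not exceed n_sites")
  if (cfg$drift_target_pct < 0 || cfg$drift_target_pct > 100)
    stop("drift_target_pct must lie in [0, 100]")
  if (cfg$dropout_prob < 0 || cfg$dropout_prob > 1 ||
      cfg$dropout_site_fraction < 0 || cfg$dropout_site_fraction > 1 ||
      cfg$tissue_affected_fraction < 0 || cfg$tissue_affected_fraction > 1)
    stop("probabilities must lie in [0, 1]")
  if (diff(cfg$age_range_days) <= 0 || cfg$age_range_days[1] <= 0)
    stop("age_range_days must be an increasing positive range")
  structure(cfg, class = "SyntheticConfig")
}

#' The S1 preset: 200 samples, 2000 sites, 40 informative, depth 30
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_config()].
#' @return a `SyntheticConfig`.
#' @export
preset_s1 <- function(seed = 1L, ...) synthetic_config(seed = seed, ...)

#' Simulate an age-structured RRBS cohort
#'
#' Informative site i follows the mean trajectory
#' `m_i(age) = m0_i + s_i * age`, with the slope signed toward
#' `drift_target_pct` and the trajectory clipped to \[0, 100\];
#' non-informative sites stay at their baseline `m0` (drawn from a bimodal
#' beta, mimicking the hypo/hyper-methylated genome). Tissue and batch
#' offsets are added on the mean scale before read sampling. Per cell, read
#' depth is negative-binomial and methylated reads are binomial(depth,
#' m/100); cells with sampled depth 0 or hit by dropout are unobserved.
#'
#' @param config a `SyntheticConfig`.
#' @return list with `matrix` (a `MethylationMatrix`), `metadata` (its
#'   sample table), `truth` (data.frame of informative sites: chrom, pos,
#'   key, baseline `m0`, true slope `slope_pct_per_day`) and `mean_pct`
#'   (the noise-free generative mean methylation per cell, for
#'   noise-floor/convergence checks).
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$n_samples; p <- config$n_sites

  ## site coordinates: autosomes only, unique positions
  chrom <- sample(paste0("chr", 1:19), p, replace = TRUE)
  pos <- as.integer(sample(1e4:2e8, p))
  while (anyDuplicated(site_key(chrom, pos)))
    pos[duplicated(site_key(chrom, pos))] <-
      as.integer(sample(1e4:2e8, sum(duplicated(site_key(chrom, pos)))))
  ord <- site_order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  keys <- site_key(chrom, pos)

  ## baselines and informative drift
  m0 <- 100 * rbeta(p, 0.4, 0.4)
  info <- sort(sample.int(p, config$n_informative))
  slope <- numeric(p)
  mag <- runif(config$n_informative, config$slope_range_pct_per_day[1],
               config$slope_range_pct_per_day[2])
  slope[info] <- sign(config$drift_target_pct - m0[info]) * mag
  slope[info][slope[info] == 0] <- mag[slope[info] == 0]

  ## sample metadata
  tissue <- rep_len(names(config$tissues), n)
  age <- round(runif(n, config$age_range_days[1], config$age_range_days[2]))
  batch <- rep_len(seq_len(config$n_batches), n)
  metadata <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)), tissue = tissue,
    age_days = age, sex = rep_len(c("male", "female"), n),
    strain = "C57Bl/6", condition = "untreated_wildtype", batch = batch)

  ## tissue offsets on a random site subset; batch offsets genome-wide
  affected <- runif(p) < config$tissue_affected_fraction
  tissue_off <- sapply(names(config$tissues), function(tt) {
    off <- numeric(p)
    off[affected] <- rnorm(sum(affected), 0, config$tissues[[tt]])
    off
  })
  batch_off <- matrix(rnorm(config$n_batches * p, 0, config$batch_sd),
                      config$n_batches, p)

  ## mean methylation per cell, clipped to [0, 100]
  mean_m <- outer(age, slope) + rep(m0, each = n) +
    t(tissue_off[, tissue]) + batch_off[batch, , drop = FALSE]
  mean_m <- matrix(pmin(100, pmax(0, mean_m)), n, p)

  depth <- matrix(rnbinom(n * p, mu = config$depth_mean,
                          size = config$depth_dispersion), n, p)
  ## site-structured dropout: a small fraction of "variably covered" sites
  ## absorbs the whole marginal dropout rate, so a stable common core
  ## survives the all-samples intersection (the RRBS phenomenon emulated)
  site_rate <- numeric(p)
  if (config$dropout_prob > 0 && config$dropout_site_fraction > 0) {
    variable <- runif(p) < config$dropout_site_fraction
    site_rate[variable] <- min(1, config$dropout_prob /
                                  config$dropout_site_fraction)
  }
  drop_mask <- matrix(runif(n * p) < rep(site_rate, each = n), n, p)
  observed <- depth >= 1L & !drop_mask
  dimnames(observed) <- list(metadata$sample_id, keys)
  meth <- matrix(0L, n, p)
  meth[observed] <- rbinom(sum(observed), depth[observed],
                           mean_m[observed] / 100)
  pct <- matrix(NA_real_, n, p, dimnames = list(metadata$sample_id, keys))
  pct[observed] <- 100 * meth[observed] / depth[observed]
  coverage <- matrix(0L, n, p, dimnames = dimnames(pct))
  coverage[observed] <- depth[observed]
  meth_mat <- matrix(0L, n, p, dimnames = dimnames(pct))
  meth_mat[observed] <- meth[observed]

  mm <- new_methylation_matrix(metadata, data.frame(chrom = chrom, pos = pos),
                               pct, coverage, observed)
  mm$meth_counts <- meth_mat  # kept so fixture files can be emitted exactly
  dimnames(mean_m) <- dimnames(pct)
  list(matrix = mm, metadata = metadata,
       truth = data.frame(chrom = chrom[info], pos = pos[info],
                          key = keys[info], m0 = m0[info],
                          slope_pct_per_day = slope[info]),
       mean_pct = mean_m)
}

#' Write a simulated cohort as bismark coverage fixtures
#'
#' Emits one six-column bismark coverage file per sample (only observed
#' cells) plus a `metadata.tsv`, all parseable by [read_bismark_coverage()]
#' and [build_matrix()]; the read-back matrix equals the generated one at
#' every observed cell.
#'
#' @param cohort output of [simulate_cohort()].
#' @param directory output directory (created if needed).
#' @return invisible character vector of the coverage file paths.
#' @export
write_fixture_files <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  mm <- cohort$matrix
  if (is.null(mm$meth_counts))
    stop("cohort matrix lacks methylated read counts")
  paths <- character(nrow(mm$samples))
  for (i in seq_len(nrow(mm$samples))) {
    id <- mm$samples$sample_id[i]
    obs <- which(mm$mask[i, ])
    s <- data.frame(chrom = mm$sites$chrom[obs], pos = mm$sites$pos[obs],
                    meth = mm$meth_counts[i, obs],
                    unmeth = mm$coverage[i, obs] - mm$meth_counts[i, obs],
                    pct = mm$pct[i, obs])
    paths[i] <- file.path(directory, paste0(id, ".cov"))
    write_bismark_coverage(new_sample_methylome(id, s), paths[i])
  }
  md <- cohort$metadata
  data.table::fwrite(md, file.path(directory, "metadata.tsv"), sep = "\t")
  invisible(paths)
}
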
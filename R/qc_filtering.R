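## Sample- and site-level inclusion rules and the tissue-stratified split.
## Both thresholds use strict inequalities: samples with *fewer than*
## `min_sites` covered CpGs are dropped, and sites under-covered in *more
## than* `max_low_fraction` of samples are dropped.

new_qc_report <- function(step, ...) {
  structure(c(list(step = step), list(...)), class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat("<QCReport>", x$step, "\n")
  for (f in setdiff(names(x), "step"))
    if (!is.list(x[[f]]) && length(x[[f]]) <= 6)
      cat(" ", f, "=", paste(x[[f]], collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a `QCReport`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
qc_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Filter samples by number of covered CpG sites
#'
#' A sample is kept iff its number of sites with coverage at least
#' `min_read_depth` is at least `min_sites` — i.e. samples with *fewer than*
#' `min_sites` covered sites are excluded, so the boundary sample with
#' exactly `min_sites` is retained. The canonical whole-lifespan clock
#' threshold is 2e6 CpGs at depth >= 1.
#'
#' @param methylomes list of `SampleMethylome` objects.
#' @param min_sites minimum number of covered sites (default 2e6).
#' @param min_read_depth read depth defining "covered" (default 1).
#' @return list with `methylomes` (kept) and `report` (a `QCReport`).
#' @export
filter_samples_by_site_count <- function(methylomes, min_sites = 2e6,
                                         min_read_depth = 1L) {
  stopifnot(min_sites >= 1)
  counts <- vapply(methylomes, function(m)
    sum(m$sites$meth + m$sites$unmeth >= min_read_depth), integer(1))
  ids <- vapply(methylomes, function(m) m$sample_id, character(1))
  keep <- counts >= min_sites
  report <- new_qc_report("filter_samples_by_site_count",
                          min_sites = min_sites,
                          min_read_depth = min_read_depth,
                          n_total = length(methylomes),
                          n_kept = sum(keep), n_excluded = sum(!keep),
                          samples_in = ids[keep],
                          samples_out = if (any(!keep))
                            setNames(as.list(sprintf(
                              "%d covered sites < %g", counts[!keep], min_sites)),
                              ids[!keep]) else list())
  if (!any(keep)) {
    cond <- simpleError(sprintf(
      "all %d samples excluded by the >= %g covered-sites filter",
      length(methylomes), min_sites))
    cond$report <- report
    stop(cond)
  }
  list(methylomes = methylomes[keep], report = report)
}

#' Soft coverage cutoff on sites
#'
#' Excludes a CpG site iff the number of samples with coverage below
#' `min_cov` at that site is *greater than* `max_low_fraction * n_samples`.
#' A masked (unobserved) cell counts as coverage 0. With the defaults this is
#' the "<5x coverage in more than 90% of samples" rule: for 10 samples a site
#' under-covered in all 10 is excluded (10 > 9) but one under-covered in
#' exactly 9 is retained (9 is not > 9).
#'
#' @param matrix a `MethylationMatrix`.
#' @param min_cov minimum per-cell read depth (default 5).
#' @param max_low_fraction tolerated fraction of low-coverage samples
#'   (default 0.9, strict).
#' @return list with `matrix` (filtered) and `report`.
#' @export
soft_coverage_cutoff <- function(matrix, min_cov = 5L, max_low_fraction = 0.9) {
  if (nrow(matrix$samples) == 0) stop("matrix has no samples")
  n <- nrow(matrix$samples)
  n_low <- colSums(matrix$coverage < min_cov | !matrix$mask)
  keep <- !(n_low > max_low_fraction * n)
  if (!any(keep)) warning("soft coverage cutoff removed every site")
  report <- new_qc_report("soft_coverage_cutoff", min_cov = min_cov,
                          max_low_fraction = max_low_fraction,
                          sites_before = ncol(matrix$pct),
                          sites_after = sum(keep))
  list(matrix = subset_matrix(matrix, sites = which(keep)), report = report)
}

#' Restrict to sites observed in every sample
#'
#' Returns the matrix restricted to the intersection of observed site sets
#' across samples (the fully-observed submatrix used for clock training).
#' Errors unless the intersection is strictly larger than `min_common`
#' (default 100,000; set 0 for toy data).
#'
#' @param matrix a `MethylationMatrix`.
#' @param min_common minimum required intersection size (strict).
#' @return list with `matrix` (fully observed) and `report`.
#' @export
common_sites <- function(matrix, min_common = 100000) {
  if (nrow(matrix$samples) == 0) stop("matrix has no samples")
  keep <- colSums(matrix$mask) == nrow(matrix$samples)
  if (sum(keep) <= min_common)
    stop(sprintf("only %d sites are covered in all samples (need > %g)",
                 sum(keep), min_common))
  report <- new_qc_report("common_sites", min_common = min_common,
                          sites_before = ncol(matrix$pct),
                          sites_after = sum(keep))
  list(matrix = subset_matrix(matrix, sites = which(keep)), report = report)
}

#' Tissue-stratified train/test split
#'
#' Within each stratum, `round(n * test_fraction)` samples are drawn into
#' the test set (without replacement, single seeded generator); the rest
#' train. The split is disjoint, exhaustive and deterministic for a fixed
#' seed. A stratum of one sample goes to training with a warning.
#'
#' @param metadata sample metadata data.frame.
#' @param test_fraction fraction held out (default 0.2).
#' @param stratify_key metadata column to stratify on (default "tissue").
#' @param seed integer seed.
#' @return list with character vectors `train` and `test` of sample ids.
#' @export
stratified_split <- function(metadata, test_fraction = 0.2,
                             stratify_key = "tissue", seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  set.seed(seed)
  test <- character(0)
  for (g in unique(metadata[[stratify_key]])) {
    ids <- metadata$sample_id[metadata[[stratify_key]] == g]
    if (length(ids) == 1) {
      warning("stratum '", g, "' has a single sample; assigned to training")
      next
    }
    n_test <- round(length(ids) * test_fraction)
    if (n_test > 0) test <- c(test, sample(ids, n_test))
  }
  list(train = setdiff(metadata$sample_id, test), test = test)
}

#' Flag PCA outlier samples (optional batch-effect screen)
#'
#' Principal components of the fully-observed percent-methylation matrix;
#' samples beyond `k` median-absolute-deviations from the median on PC1 or
#' PC2 are flagged. This is a deliberately conservative, algorithmic
#' stand-in for figure-based batch-effect exclusion and is OFF by default in
#' the pipeline.
#'
#' @param matrix a fully-observed `MethylationMatrix`.
#' @param k MAD multiplier (default 6).
#' @return logical vector (named by sample id), TRUE = outlier.
#' @export
pca_outlier_flag <- function(matrix, k = 6) {
  if (any(!matrix$mask)) stop("pca_outlier_flag needs a fully-observed matrix")
  pcs <- stats::prcomp(matrix$pct, center = TRUE, scale. = FALSE, rank. = 2)$x
  flag <- rep(FALSE, nrow(pcs))
  for (j in seq_len(ncol(pcs))) {
    v <- pcs[, j]
    m <- stats::mad(v)
    if (m > 0) flag <- flag | abs(v - median(v)) > k * m
  }
  setNames(flag, matrix$samples$sample_id)
}
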
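# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the code paths they check: the MWU oracle
# enumerates labelings with combn (the implementation uses a subset-sum DP),
# the filter oracles loop cell by cell, and regression oracles use normal
# equations / closed forms.

# Exact two-tailed Mann-Whitney p by full enumeration of group labelings.
mwu_enum_oracle <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)])
  combs <- utils::combn(length(pooled), n_a)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  p_le <- mean(ws <= w_obs + eps)
  p_ge <- mean(ws >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

# Yates chi-square from the closed formula, straight off a 2x2 table.
yates_oracle <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  num <- abs(a * d - b * c_) - N / 2
  stat <- if (num <= 0) 0 else
    N * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# Build a MethylationMatrix directly from a pct matrix (counts synthesized
# at high depth so stored pct is exact to < 0.005).
toy_matrix <- function(pct, ages, tissue = NULL, coverage = NULL,
                       mask = NULL, sample_id = NULL, chrom = NULL,
                       pos = NULL) {
  n <- nrow(pct); p <- ncol(pct)
  if (is.null(sample_id)) sample_id <- sprintf("S%02d", seq_len(n))
  if (is.null(tissue)) tissue <- rep("liver", n)
  if (is.null(coverage)) coverage <- matrix(20000L, n, p)
  if (is.null(mask)) mask <- matrix(TRUE, n, p)
  if (is.null(chrom)) chrom <- rep("chr1", p)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = p)
  md <- data.frame(sample_id = sample_id, tissue = tissue, age_days = ages,
                   sex = "male", strain = "C57Bl/6",
                   condition = "untreated_wildtype")
  keys <- site_key(chrom, pos)
  dimnames(pct) <- dimnames(coverage) <- dimnames(mask) <-
    list(sample_id, keys)
  pct[!mask] <- NA_real_
  coverage[!mask] <- 0L
  rrbsclock:::new_methylation_matrix(md, data.frame(chrom = chrom, pos = pos),
                                     pct, coverage, mask)
}

toy_clock <- function(weights, intercept = 0, chrom = NULL, pos = NULL,
                      train_mean = NA_real_, name = "toy", ...) {
  p <- length(weights)
  if (is.null(chrom)) chrom <- rep("chr1", p)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = p)
  clock_definition(name, data.frame(chrom = chrom, pos = pos,
                                    weight = weights,
                                    train_mean = train_mean),
                   intercept = intercept, ...)
}

toy_methylome <- function(chrom, pos, meth, unmeth, sample_id = "T1") {
  rrbsclock:::new_sample_methylome(
    sample_id,
    data.frame(chrom = chrom, pos = as.integer(pos), meth = as.integer(meth),
               unmeth = as.integer(unmeth),
               pct = 100 * meth / (meth + unmeth)))
}

write_cov_lines <- function(lines, path = tempfile(fileext = ".cov")) {
  writeLines(lines, path)
  path
}

# Small strong-signal cohort used by training and robustness tests.
toy_cohort <- function(seed = 11, n_samples = 60, n_sites = 120,
                       n_informative = 6) {
  simulate_cohort(synthetic_config(
    n_samples = n_samples, n_sites = n_sites, n_informative = n_informative,
    seed = seed))
}
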
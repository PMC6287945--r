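test_that("bismark coverage parsing: counts are authoritative", {
  path <- write_cov_lines(c("chr1\t3000827\t3000827\t75.0\t3\t1",
                            "chr2\t500\t500\t100.0\t4\t0"))
  m <- read_bismark_coverage(path)
  expect_s3_class(m, "SampleMethylome")
  expect_equal(nrow(m$sites), 2)
  expect_equal(m$sites$chrom[1], "chr1")
  expect_equal(m$sites$pos[1], 3000827L)
  expect_equal(m$sites$meth[1], 3L)
  expect_equal(m$sites$unmeth[1], 1L)
  expect_equal(m$sites$pct[1], 75)

  # percent column inconsistent with counts -> recomputed with a warning
  path2 <- write_cov_lines("chr1\t100\t100\t50.0\t3\t1")
  expect_warning(m2 <- read_bismark_coverage(path2), "inconsistent")
  expect_equal(m2$sites$pct, 75)
})

test_that("bismark coverage parsing: malformed input errors name the line", {
  bad_count <- write_cov_lines(c("chr1\t100\t100\t75.0\t3\t1",
                                 "chr1\t200\t200\t50.0\t-1\t1"))
  expect_error(read_bismark_coverage(bad_count), "line 2.*negative")
  bad_cols <- write_cov_lines(c("chr1\t100\t100\t75.0\t3\t1",
                                "chr1\t200\t200\t50.0\t3"))
  expect_error(read_bismark_coverage(bad_cols), "line 2")
  empty <- write_cov_lines(character(0))
  expect_warning(m <- read_bismark_coverage(empty), "empty")
  expect_equal(nrow(m$sites), 0)
})

test_that("contig exclusion, chrom normalization and min_coverage", {
  path <- write_cov_lines(c("1\t100\t100\t100.0\t2\t0",
                            "chrX\t100\t100\t0.0\t0\t5",
                            "chrM\t100\t100\t0.0\t0\t5",
                            "MT\t200\t200\t0.0\t0\t5",
                            "chr2\t50\t50\t50.0\t1\t1"))
  m <- read_bismark_coverage(path, min_coverage = 2)
  expect_setequal(site_key(m$sites$chrom, m$sites$pos),
                  c("chr1:100", "chr2:50"))
  m5 <- read_bismark_coverage(path, min_coverage = 3,
                              exclude_contigs = character(0))
  expect_true("chrX:100" %in% site_key(m5$sites$chrom, m5$sites$pos))
  expect_false("chr2:50" %in% site_key(m5$sites$chrom, m5$sites$pos))
})

test_that("coverage round trip preserves every (site, meth, unmeth) triple", {
  set.seed(5)
  n <- 50
  m <- toy_methylome(sample(c("chr1", "chr2", "chr11"), n, TRUE),
                     sample(1e6, n), sample(0:20, n, TRUE),
                     sample(0:20, n, TRUE) + 1L)
  path <- tempfile(fileext = ".cov")
  write_bismark_coverage(m, path)
  back <- read_bismark_coverage(path, sample_id = "T1")
  key <- function(s) site_key(s$chrom, s$pos)
  i <- match(key(m$sites), key(back$sites))
  expect_false(anyNA(i))
  expect_equal(back$sites$meth[i], m$sites$meth)
  expect_equal(back$sites$unmeth[i], m$sites$unmeth)
})

test_that("merge_strands sums dinucleotide counts onto the forward anchor", {
  m <- toy_methylome(c("chr1", "chr1", "chr1"), c(100, 101, 300),
                     c(3, 2, 4), c(1, 2, 0))
  st <- data.frame(chrom = "chr1", pos = c(100, 101, 300),
                   strand = c("+", "-", "+"))
  merged <- merge_strands(m, st)
  expect_equal(nrow(merged$sites), 2)
  a <- merged$sites[merged$sites$pos == 100, ]
  expect_equal(a$meth, 5)
  expect_equal(a$unmeth, 3)
  expect_equal(a$pct, 62.5)
  # forward-only site untouched
  b <- merged$sites[merged$sites$pos == 300, ]
  expect_equal(c(b$meth, b$unmeth), c(4, 0))
})

test_that("merge_strands conserves total read counts on random input", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 30
    pos <- sort(sample(seq(10, 4000, by = 2), n))
    strand <- sample(c("+", "-"), n, TRUE)
    pos[strand == "-"] <- pos[strand == "-"] + 1L
    m <- toy_methylome(rep("chr3", n), pos, sample(0:9, n, TRUE),
                       sample(0:9, n, TRUE) + 1L)
    st <- data.frame(chrom = "chr3", pos = pos, strand = strand)
    merged <- merge_strands(m, st)
    expect_equal(sum(merged$sites$meth), sum(m$sites$meth))
    expect_equal(sum(merged$sites$unmeth), sum(m$sites$unmeth))
  }
  # unknown strand: kept as own anchor, with a warning
  m <- toy_methylome("chr1", 500, 2, 2)
  expect_warning(out <- merge_strands(m, data.frame(chrom = "chr9", pos = 1,
                                                    strand = "+")),
                 "unknown strand")
  expect_equal(out$sites$pos, 500)
})

test_that("build_matrix honours site policy, ordering and metadata checks", {
  m1 <- toy_methylome("chr1", c(100, 200, 300, 400, 500), rep(3, 5),
                      rep(1, 5), "A")
  m2 <- toy_methylome("chr1", c(200, 300, 400), rep(1, 3), rep(3, 3), "B")
  md <- data.frame(sample_id = c("A", "B"), tissue = "liver",
                   age_days = c(100, 200), sex = "male", strain = "s",
                   condition = "untreated_wildtype")
  un <- build_matrix(list(m1, m2), md, "union")
  expect_equal(dim(un$pct), c(2, 5))
  expect_equal(sum(!un$mask), 2)
  inter <- build_matrix(list(m1, m2), md, "intersection")
  expect_equal(dim(inter$pct), c(2, 3))
  expect_true(all(inter$mask))
  expect_error(build_matrix(list(m1, toy_methylome("chr1", 1, 1, 1, "S9")),
                            md), "S9")
  expect_error(build_matrix(list(m1), rbind(md, md[1, ])), "duplicate")
  # numeric-aware chromosome order: chr2 before chr10
  m3 <- toy_methylome(c("chr10", "chr2"), c(5, 9), c(1, 1), c(1, 1), "C")
  mm <- build_matrix(list(m3), data.frame(
    sample_id = "C", tissue = "t", age_days = 1, sex = "f", strain = "s",
    condition = "untreated_wildtype"))
  expect_equal(mm$sites$chrom, c("chr2", "chr10"))
})

test_that("build_matrix intersection equals brute-force set intersection", {
  set.seed(13)
  for (rep in 1:5) {
    sets <- lapply(1:3, function(i) sort(sample(100 * (1:10),
                                                sample(3:8, 1))))
    ms <- lapply(seq_along(sets), function(i)
      toy_methylome(rep("chr1", length(sets[[i]])), sets[[i]],
                    rep(1, length(sets[[i]])), rep(1, length(sets[[i]])),
                    paste0("S", i)))
    md <- data.frame(sample_id = paste0("S", 1:3), tissue = "t",
                     age_days = 1:3, sex = "m", strain = "s",
                     condition = "untreated_wildtype")
    mm <- build_matrix(ms, md, "intersection")
    expect_setequal(mm$sites$pos, Reduce(intersect, sets))
  }
})

test_that("clock definition files round-trip exactly", {
  set.seed(3)
  clock <- toy_clock(rnorm(20) * exp(rnorm(20, 0, 3)), intercept = 234.64,
                     chrom = sample(paste0("chr", 1:19), 20, TRUE),
                     pos = sample(1e8, 20), train_mean = runif(20, 0, 100),
                     transform = transform_spec("exp_linear", a = 1.5,
                                                b = -0.25),
                     min_site_fraction = 0.85,
                     strand_policy = "dinucleotide_merged")
  path <- tempfile(fileext = ".tsv")
  write_clock_definition(clock, path)
  back <- read_clock_definition(path)
  expect_identical(back$sites$weight, clock$sites$weight)
  expect_identical(back$sites$train_mean, clock$sites$train_mean)
  expect_identical(back$intercept, clock$intercept)
  expect_identical(back$transform, clock$transform)
  expect_identical(back$min_site_fraction, clock$min_site_fraction)
  expect_identical(back$strand_policy, clock$strand_policy)
  expect_equal(site_key(back$sites$chrom, back$sites$pos),
               site_key(clock$sites$chrom, clock$sites$pos))
})

test_that("clock definition parsing rejects malformed files", {
  path <- tempfile()
  writeLines(c("#intercept=10", "chrom\tpos_1based\tweight\ttrain_mean",
               "chr1\t100\t2.0\tNA", "chr1\t100\t1.0\tNA"), path)
  expect_error(read_clock_definition(path), "duplicate")
  writeLines(c("#intercept=10", "chrom\tpos_1based\ttrain_mean",
               "chr1\t100\tNA"), path)
  expect_error(read_clock_definition(path), "weight")
  writeLines(c("#intercept=10", "#transform=sqrtish",
               "chrom\tpos_1based\tweight", "chr1\t100\t2.0"), path)
  expect_error(read_clock_definition(path), "unknown transform")
  # minimal file: transform defaults to identity, min_site_fraction to 0.9
  writeLines(c("#intercept=10", "chrom\tpos_1based\tweight",
               "chr1\t100\t2.0"), path)
  cl <- read_clock_definition(path)
  expect_equal(cl$transform$form, "identity")
  expect_equal(cl$min_site_fraction, 0.9)
  pred <- predict_age(cl, toy_methylome("chr1", 100, 1, 1))
  expect_equal(pred$predicted_age_days, 10 + 2 * 50)
})

test_that("clock_definition validates its invariants", {
  expect_error(toy_clock(c(1, 2), intercept = Inf), "finite")
  expect_error(toy_clock(c(0, 0)), "not all be zero")
  expect_error(clock_definition("d", data.frame(
    chrom = c("chr1", "1"), pos = c(5, 5), weight = c(1, 2)), 0),
    "duplicate")
})
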
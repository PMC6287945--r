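# Synthetic stand-ins for the published clock-definition tables (the real
# supplementary tables are not redistributable here). They encode the same
# structural facts -- site counts (435 / 90 / 329), a five-site overlap
# between the multi-tissue and blood clocks, zero overlap with the young
# multi-tissue clock, and the maximal-|weight| site at chr8:110168311 --
# so the definition-file machinery is exercised on realistic shapes.
# SYNTHETIC: site coordinates and weights are generated, not published data.
make_synthetic_published_clocks <- function(dir = tempfile("clocks")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(20181114)
  rand_sites <- function(n, offset) {
    data.frame(chrom = sample(paste0("chr", 1:19), n, TRUE),
               pos = sample(seq(offset, offset + 5e7), n))
  }
  shared <- data.frame(chrom = c("chr2", "chr4", "chr9", "chr11", "chr15"),
                       pos = c(164168131L, 5201000L, 77000021L, 1200457L,
                               90211345L))
  wlmt_sites <- rbind(shared, rand_sites(429, 1e6),
                      data.frame(chrom = "chr8", pos = 110168311L))
  w <- rnorm(435, 0, 1.5)
  w[435] <- 12  # maximal |weight| at the chr8 anchor site
  wlmt <- clock_definition("wlmt_synthetic", cbind(wlmt_sites, weight = w),
                           intercept = 234.64)
  blood <- clock_definition(
    "blood_synthetic", cbind(rbind(shared, rand_sites(85, 6e7)),
                             weight = rnorm(90)),
    intercept = 30,
    transform = transform_spec("exp_linear", a = 0.16, b = 4.2))
  yomt <- clock_definition(
    "yomt_synthetic", cbind(rand_sites(329, 1.2e8), weight = rnorm(329)),
    intercept = 12,
    transform = transform_spec("logistic", a = 0.5, b = 0, c = 1200))
  paths <- c(wlmt = file.path(dir, "wlmt_synthetic.tsv"),
             blood = file.path(dir, "blood_synthetic.tsv"),
             yomt = file.path(dir, "yomt_synthetic.tsv"))
  write_clock_definition(wlmt, paths["wlmt"])
  write_clock_definition(blood, paths["blood"])
  write_clock_definition(yomt, paths["yomt"])
  paths
}
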
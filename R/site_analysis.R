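## Clock-site set comparisons, gene-level overlap testing with Yates
## chi-square, CpG island/shore/shelf/open-sea annotation, and chromosome
## representation.

clock_site_keys <- function(clock) site_key(clock$sites$chrom, clock$sites$pos)

#' Exact CpG-site overlap between two clocks
#'
#' Intersection of (chrom, pos) pairs after chromosome-name normalization.
#'
#' @param clock_a,clock_b `ClockDefinition` objects.
#' @return data.frame of shared sites (`chrom`, `pos`), possibly empty.
#' @export
site_overlap <- function(clock_a, clock_b) {
  shared <- intersect(clock_site_keys(clock_a), clock_site_keys(clock_b))
  s <- clock_a$sites[clock_site_keys(clock_a) %in% shared,
                     c("chrom", "pos"), drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Yates-corrected chi-square test of gene-set overlap
#'
#' Builds the 2x2 contingency table of membership in A versus membership in
#' B over a gene universe and applies the continuity-corrected chi-square
#' `X^2 = N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of
#' freedom (two-tailed). The correction floors at zero: when
#' `|ad - bc| <= N/2` the statistic is 0 and p = 1.
#'
#' @param genes_a,genes_b character gene sets, both subsets of `universe`.
#' @param universe character gene universe (>= 4 genes).
#' @return an `OverlapResult`: `shared`, per-set counts, `table` (2x2),
#'   `statistic`, `p_value`.
#' @export
gene_overlap_test <- function(genes_a, genes_b, universe) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  universe <- unique(universe)
  if (length(universe) < 4) stop("universe must contain at least 4 genes")
  if (!all(genes_a %in% universe) || !all(genes_b %in% universe))
    stop("gene sets must be subsets of the universe")
  in_a <- universe %in% genes_a
  in_b <- universe %in% genes_b
  a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
  c_ <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(c("in_A", "not_A"), c("in_B", "not_B")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined: a table margin is zero")
  N <- a + b + c_ + d
  num <- abs(a * d - b * c_) - N / 2
  stat <- if (num <= 0) 0 else
    N * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  structure(list(shared = intersect(genes_a, genes_b),
                 n_a = length(genes_a), n_b = length(genes_b),
                 n_universe = N, table = tab, statistic = stat,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("<OverlapResult> |A|=%d |B|=%d shared=%d of %d; Yates X2=%.4g, p=%.3g\n",
              x$n_a, x$n_b, length(x$shared), x$n_universe, x$statistic,
              x$p_value))
  invisible(x)
}

#' Read a BED interval file (0-based half-open) as 1-based inclusive
#'
#' @param path BED path (first three columns used).
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 3) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = normalize_chrom(dt[[1]]),
                    start = as.integer(dt[[2]]) + 1L,
                    end = as.integer(dt[[3]]))
  if (ncol(dt) >= 4 && !all(is.na(dt[[4]]))) out$name <- as.character(dt[[4]])
  out
}

intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(intervals$chrom,
                         IRanges::IRanges(intervals$start, intervals$end))
}

#' Annotate CpG sites by CpG-island context
#'
#' Standard island/shore/shelf/open-sea partition: a site inside a (merged)
#' island interval is `island`; within 2 kb of an island edge, `shore`;
#' between 2 and 4 kb, `shelf`; beyond 4 kb (or on a contig without
#' annotation, with a warning), `open_sea`. Labels are exhaustive and
#' mutually exclusive, so the fractions sum to one.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based), or a
#'   `ClockDefinition`.
#' @param islands island intervals: a BED path or a data.frame from
#'   [read_bed()] (1-based inclusive).
#' @param shore_bp,shelf_bp shore and shelf widths in bp (defaults 2000 and
#'   2000, i.e. shelves span 2-4 kb).
#' @return a `GenomicContext`: list with `labels` (factor per site) and
#'   `fractions` (named numeric summing to 1).
#' @export
annotate_genomic_context <- function(sites, islands, shore_bp = 2000L,
                                     shelf_bp = 2000L) {
  if (inherits(sites, "ClockDefinition")) sites <- sites$sites
  if (is.character(islands)) islands <- read_bed(islands)
  islands$chrom <- normalize_chrom(islands$chrom)
  isl <- GenomicRanges::reduce(intervals_to_granges(islands))
  gr <- GenomicRanges::GRanges(normalize_chrom(sites$chrom),
                               IRanges::IRanges(sites$pos, sites$pos))
  labels <- rep("open_sea", length(gr))
  known <- as.character(GenomicRanges::seqnames(gr)) %in%
    as.character(unique(GenomicRanges::seqnames(isl)))
  if (any(!known))
    warning(sum(!known), " site(s) on contigs absent from the island ",
            "annotation; labelled open_sea")
  ## seqlevel mismatches are expected (handled above as open_sea), so the
  ## GenomicRanges advisory warning is suppressed
  inside <- suppressWarnings(GenomicRanges::countOverlaps(gr, isl) > 0)
  labels[inside] <- "island"
  todo <- known & !inside
  if (any(todo)) {
    hits <- suppressWarnings(GenomicRanges::distanceToNearest(gr[todo], isl))
    d <- rep(NA_real_, sum(todo))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    ## distanceToNearest: adjacent ranges have distance 0, so a site k bp
    ## beyond an island edge has distance k-1; "within 2000 bp" = d < 2000
    lab <- ifelse(is.na(d), "open_sea",
                  ifelse(d < shore_bp, "shore",
                         ifelse(d < shore_bp + shelf_bp, "shelf", "open_sea")))
    labels[todo] <- lab
  }
  labels <- factor(labels, levels = c("island", "shore", "shelf", "open_sea"))
  structure(list(labels = labels,
                 fractions = prop.table(table(labels))),
            class = "GenomicContext")
}

#' @export
print.GenomicContext <- function(x, ...) {
  f <- x$fractions
  cat(sprintf("<GenomicContext> %d sites: %s\n", length(x$labels),
              paste(sprintf("%s %.0f%%", names(f), 100 * f), collapse = ", ")))
  invisible(x)
}

#' Map CpG sites to genes by interval containment
#'
#' A site maps to every gene whose (optionally promoter-extended) interval
#' contains it; multi-gene hits are allowed.
#'
#' @param sites data.frame with `chrom`, `pos`, or a `ClockDefinition`.
#' @param genes gene intervals: a BED path (with a name column) or a
#'   data.frame with `chrom`, `start`, `end`, `name` (1-based inclusive).
#' @param promoter_bp extension added upstream and downstream of each gene
#'   interval (default 0).
#' @return character vector of unique gene names hit by the sites.
#' @export
sites_to_genes <- function(sites, genes, promoter_bp = 0L) {
  if (inherits(sites, "ClockDefinition")) sites <- sites$sites
  if (is.character(genes)) genes <- read_bed(genes)
  if (!"name" %in% names(genes)) stop("gene intervals need a 'name' column")
  genes$chrom <- normalize_chrom(genes$chrom)
  gg <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - promoter_bp),
                     genes$end + promoter_bp))
  gr <- GenomicRanges::GRanges(normalize_chrom(sites$chrom),
                               IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(gr, gg)
  sort(unique(genes$name[S4Vectors::subjectHits(hits)]))
}

#' Per-chromosome clock-site counts and completeness
#'
#' Counts clock sites per chromosome (zero counts included for expected
#' chromosomes with no sites). The completeness flag is true iff every
#' expected chromosome carries at least one site. Clocks containing sex
#' chromosome sites violate the sex-independent construction rule and raise
#' an error.
#'
#' @param clock a `ClockDefinition`.
#' @param expected_chroms chromosomes expected to be represented (default
#'   the 19 mouse autosomes).
#' @return list with `counts` (named integer vector over
#'   `expected_chroms` plus any extra autosomes observed) and `complete`.
#' @export
chromosome_representation <- function(clock,
                                      expected_chroms = paste0("chr", 1:19)) {
  chroms <- clock$sites$chrom
  if (any(chroms %in% c("chrX", "chrY")))
    stop("clock contains sex-chromosome sites, which the construction excludes")
  all_chroms <- union(expected_chroms, unique(chroms))
  counts <- setNames(integer(length(all_chroms)), all_chroms)
  tab <- table(chroms)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts,
       complete = all(counts[expected_chroms] >= 1L))
}
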
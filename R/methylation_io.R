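## Readers/writers for per-sample methylation calls, clock definitions and
## cohort-level matrices. Coordinates are 1-based inclusive throughout
## (genome-browser style, matching bismark coverage output); BED import is
## converted at the boundary.

#' Default contigs excluded from clock construction
#'
#' Mitochondrial and sex-chromosome sites are removed by default when reading
#' methylation calls, matching standard practice for sex-independent
#' multi-tissue clocks.
#' @export
DEFAULT_EXCLUDED_CONTIGS <- c("chrM", "chrX", "chrY")

#' Normalize chromosome names
#'
#' Maps bare names to the canonical "chr"-prefixed form ("1" -> "chr1",
#' "MT" -> "chrM"). Already-prefixed names pass through unchanged.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of canonical names.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  chrom[chrom %in% c("MT", "M")] <- "chrM"
  bare <- !startsWith(chrom, "chr")
  chrom[bare] <- paste0("chr", chrom[bare])
  chrom
}

#' Site keys ("chr1:3000827") for (chrom, pos) pairs
#' @param chrom chromosome names (canonicalized).
#' @param pos 1-based positions.
#' @return character vector of keys, one per site.
#' @export
site_key <- function(chrom, pos) {
  if (!length(chrom)) return(character(0))  # paste0 would recycle to ":"
  paste0(chrom, ":", as.integer(pos))
}

## (chrom, pos) order: numbered chromosomes numerically, then named ones
## alphabetically, positions numeric within chromosome.
site_order <- function(chrom, pos) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
  order(is.na(num), num, chrom, pos)
}

new_sample_methylome <- function(sample_id, sites) {
  stopifnot(is.data.frame(sites))
  structure(list(sample_id = sample_id, sites = sites),
            class = "SampleMethylome")
}

#' @export
print.SampleMethylome <- function(x, ...) {
  cat(sprintf("<SampleMethylome> %s: %d CpG sites, median coverage %s\n",
              x$sample_id, nrow(x$sites),
              if (nrow(x$sites)) median(x$sites$meth + x$sites$unmeth) else NA))
  invisible(x)
}

#' Read a bismark coverage file into a SampleMethylome
#'
#' Parses the six-column bismark coverage format (chrom, start, end,
#' percent methylation, methylated count, unmethylated count; start = end =
#' 1-based cytosine position). Counts are authoritative: the percent column
#' is recomputed as `100 * meth / (meth + unmeth)` and a mismatch of more
#' than 0.5 percentage points triggers a warning (upstream emitters round).
#'
#' @param path path to a tab-separated coverage file.
#' @param min_coverage minimum total read count for a site to be kept.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param exclude_contigs contigs dropped on read (default mitochondrial and
#'   sex chromosomes); set to `character(0)` to keep everything.
#' @return a `SampleMethylome`: sample id plus a data.frame with columns
#'   `chrom`, `pos`, `meth`, `unmeth`, `pct`.
#' @export
read_bismark_coverage <- function(path, min_coverage = 1L,
                                  sample_id = NULL,
                                  exclude_contigs = DEFAULT_EXCLUDED_CONTIGS) {
  stopifnot(min_coverage >= 1)
  if (is.null(sample_id))
    sample_id <- sub("\\.(cov|txt|tsv)(\\.gz)?$", "", basename(path))
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (file.size(path) == 0 || length(readLines(path, n = 1L)) == 0) {
    warning("empty coverage file: ", path)
    return(new_sample_methylome(sample_id, data.frame(
      chrom = character(0), pos = integer(0), meth = integer(0),
      unmeth = integer(0), pct = numeric(0))))
  }
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 6L)
  if (length(bad))
    stop(sprintf("malformed coverage line %d in %s: expected 6 tab-separated fields, found %d",
                 bad[1], path, nf[bad[1]]))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "pct_in",
                                        "meth", "unmeth"),
                          colClasses = list(character = 1))
  if (anyNA(dt$meth) || anyNA(dt$unmeth) || anyNA(dt$start))
    stop("malformed coverage line ",
         which(is.na(dt$meth) | is.na(dt$unmeth) | is.na(dt$start))[1],
         " in ", path, ": non-numeric field")
  neg <- which(dt$meth < 0 | dt$unmeth < 0)
  if (length(neg))
    stop(sprintf("malformed coverage line %d in %s: negative read count",
                 neg[1], path))
  dt$chrom <- normalize_chrom(dt$chrom)
  cov <- dt$meth + dt$unmeth
  pct <- ifelse(cov > 0, 100 * dt$meth / cov, NA_real_)
  mism <- which(cov > 0 & is.finite(dt$pct_in) & abs(dt$pct_in - pct) > 0.5)
  if (length(mism))
    warning(sprintf("%d line(s) in %s have a percent column inconsistent with counts (> 0.5 pp); counts used",
                    length(mism), path))
  keep <- cov >= min_coverage & !(dt$chrom %in% exclude_contigs)
  sites <- data.frame(chrom = dt$chrom[keep], pos = as.integer(dt$start[keep]),
                      meth = as.integer(dt$meth[keep]),
                      unmeth = as.integer(dt$unmeth[keep]),
                      pct = pct[keep])
  if (anyDuplicated(site_key(sites$chrom, sites$pos)))
    stop("duplicate site in coverage file: ", path)
  new_sample_methylome(sample_id, sites)
}

#' Write a SampleMethylome as a bismark coverage file
#' @param methylome a `SampleMethylome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bismark_coverage <- function(methylome, path) {
  s <- methylome$sites
  out <- data.frame(s$chrom, s$pos, s$pos,
                    ifelse(s$meth + s$unmeth > 0,
                           100 * s$meth / (s$meth + s$unmeth), 0),
                    s$meth, s$unmeth)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bismark cytosine report (strand-resolved)
#'
#' Seven columns: chrom, pos, strand, meth count, unmeth count, context,
#' trinucleotide. Only CpG-context rows are kept. The returned methylome has
#' an additional `strand` column, suitable for [merge_strands()].
#'
#' @inheritParams read_bismark_coverage
#' @param context context label to retain (default "CpG"; bismark writes
#'   "CpG"/"CHG"/"CHH").
#' @return a `SampleMethylome` whose `sites` carry a `strand` column.
#' @export
read_cytosine_report <- function(path, min_coverage = 1L, sample_id = NULL,
                                 exclude_contigs = DEFAULT_EXCLUDED_CONTIGS,
                                 context = "CpG") {
  if (is.null(sample_id))
    sample_id <- sub("\\.(txt|tsv)(\\.gz)?$", "", basename(path))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos", "strand", "meth",
                                        "unmeth", "context", "tri"),
                          colClasses = list(character = c(1, 3, 6, 7)))
  if (any(dt$meth < 0 | dt$unmeth < 0, na.rm = TRUE))
    stop("negative read count in cytosine report: ", path)
  dt <- dt[dt$context == context, ]
  dt$chrom <- normalize_chrom(dt$chrom)
  cov <- dt$meth + dt$unmeth
  keep <- cov >= min_coverage & !(dt$chrom %in% exclude_contigs)
  sites <- data.frame(chrom = dt$chrom[keep], pos = as.integer(dt$pos[keep]),
                      strand = dt$strand[keep],
                      meth = as.integer(dt$meth[keep]),
                      unmeth = as.integer(dt$unmeth[keep]),
                      pct = 100 * dt$meth[keep] / cov[keep])
  new_sample_methylome(sample_id, sites)
}

#' Merge strand-resolved CpG calls onto forward-strand anchors
#'
#' In a CpG dinucleotide the reverse-strand cytosine sits one base after the
#' forward-strand cytosine, so counts at reverse position p+1 are summed onto
#' anchor p. Total methylated and unmethylated read counts are conserved
#' exactly. Strand information comes either from a `strand` column on the
#' methylome (cytosine report input) or from `strand_table`.
#'
#' @param methylome a `SampleMethylome`.
#' @param strand_table optional data.frame (`chrom`, `pos`, `strand`) used
#'   when the methylome has no strand column. Sites with unknown strand are
#'   kept as their own anchors with a warning.
#' @return a `SampleMethylome` on forward-strand anchors.
#' @export
merge_strands <- function(methylome, strand_table = NULL) {
  s <- methylome$sites
  if (!nrow(s)) return(methylome)
  if (!"strand" %in% names(s)) {
    if (is.null(strand_table))
      stop("methylome carries no strand column and no strand_table given")
    strand_table$chrom <- normalize_chrom(strand_table$chrom)
    idx <- match(site_key(s$chrom, s$pos),
                 site_key(strand_table$chrom, strand_table$pos))
    s$strand <- strand_table$strand[idx]
  }
  unknown <- is.na(s$strand) | !(s$strand %in% c("+", "-"))
  if (any(unknown)) {
    warning(sum(unknown), " site(s) with unknown strand kept as their own anchors")
    s$strand[unknown] <- "+"
  }
  anchor <- as.integer(ifelse(s$strand == "-", s$pos - 1L, s$pos))
  key <- site_key(s$chrom, anchor)
  sums <- rowsum(cbind(meth = s$meth, unmeth = s$unmeth), group = key)
  first <- !duplicated(key)
  idx <- match(rownames(sums), key[first])
  agg <- data.frame(chrom = s$chrom[first][idx], pos = anchor[first][idx],
                    meth = as.integer(sums[, "meth"]),
                    unmeth = as.integer(sums[, "unmeth"]))
  agg$pct <- 100 * agg$meth / (agg$meth + agg$unmeth)
  agg <- agg[site_order(agg$chrom, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  new_sample_methylome(methylome$sample_id, agg)
}

#' Read a sample metadata table
#'
#' Tab-separated with columns `sample_id`, `tissue`, `age_days`, `sex`,
#' `strain`, `condition`.
#' @param path metadata TSV path.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  required <- c("sample_id", "tissue", "age_days", "sex", "strain", "condition")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1])
  if (any(!is.finite(md$age_days) | md$age_days <= 0))
    stop("age_days must be finite and positive")
  md
}

#' Assemble a cohort methylation matrix
#'
#' Builds the samples x sites percent-methylation matrix (plus a parallel
#' coverage matrix and an observed/missing mask) from per-sample methylomes.
#' Sample order follows `metadata`; sites are ordered by (chrom, pos).
#'
#' @param methylomes list of `SampleMethylome` objects.
#' @param metadata data.frame with one row per methylome `sample_id`
#'   (columns as in [read_sample_metadata()]).
#' @param site_policy `"union"` keeps every site seen in any sample (missing
#'   cells masked); `"intersection"` keeps only sites observed in all.
#' @return a `MethylationMatrix`: list with `samples` (metadata),
#'   `sites` (chrom/pos data.frame), and matrices `pct`, `coverage`, `mask`
#'   (rows = samples, columns = site keys).
#' @export
build_matrix <- function(methylomes, metadata,
                         site_policy = c("union", "intersection")) {
  site_policy <- match.arg(site_policy)
  ids <- vapply(methylomes, function(m) m$sample_id, character(1))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate metadata rows for: ",
         metadata$sample_id[duplicated(metadata$sample_id)][1])
  orphan <- setdiff(ids, metadata$sample_id)
  if (length(orphan))
    stop("sample(s) without metadata: ", paste(orphan, collapse = ", "))
  metadata <- metadata[metadata$sample_id %in% ids, , drop = FALSE]
  methylomes <- methylomes[match(metadata$sample_id, ids)]

  keys_per_sample <- lapply(methylomes, function(m) site_key(m$sites$chrom, m$sites$pos))
  keys <- if (site_policy == "union") unique(unlist(keys_per_sample))
          else Reduce(intersect, keys_per_sample)
  if (!length(keys)) {
    sites <- data.frame(chrom = character(0), pos = integer(0))
  } else {
    parts <- strsplit(keys, ":", fixed = TRUE)
    sites <- data.frame(chrom = vapply(parts, `[`, "", 1),
                        pos = as.integer(vapply(parts, `[`, "", 2)))
    ord <- site_order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    rownames(sites) <- NULL
    keys <- site_key(sites$chrom, sites$pos)
  }
  n <- nrow(metadata); p <- length(keys)
  pct <- matrix(NA_real_, n, p, dimnames = list(metadata$sample_id, keys))
  coverage <- matrix(0L, n, p, dimnames = dimnames(pct))
  for (i in seq_len(n)) {
    m <- methylomes[[i]]$sites
    j <- match(site_key(m$chrom, m$pos), keys)
    ok <- !is.na(j)
    pct[i, j[ok]] <- m$pct[ok]
    coverage[i, j[ok]] <- m$meth[ok] + m$unmeth[ok]
  }
  new_methylation_matrix(metadata, sites, pct, coverage, coverage > 0L)
}

new_methylation_matrix <- function(samples, sites, pct, coverage, mask) {
  rownames(samples) <- NULL
  x <- structure(list(samples = samples, sites = sites, pct = pct,
                      coverage = coverage, mask = mask),
                 class = "MethylationMatrix")
  validate_methylation_matrix(x)
}

validate_methylation_matrix <- function(x) {
  stopifnot(nrow(x$pct) == nrow(x$samples), ncol(x$pct) == nrow(x$sites),
            identical(dim(x$pct), dim(x$coverage)),
            identical(dim(x$pct), dim(x$mask)))
  obs <- x$pct[x$mask]
  if (length(obs) && (anyNA(obs) || any(obs < 0 | obs > 100)))
    stop("observed percent methylation outside [0, 100]")
  if (any(x$coverage[x$mask] < 1))
    stop("observed cells must have coverage >= 1")
  x
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("<MethylationMatrix> %d samples x %d sites (%.1f%% observed)\n",
              nrow(x$samples), nrow(x$sites),
              if (length(x$mask)) 100 * mean(x$mask) else 100))
  if (nrow(x$samples))
    cat("  tissues:", paste(sort(unique(x$samples$tissue)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a MethylationMatrix by samples and/or sites
#' @param x a `MethylationMatrix`.
#' @param samples sample ids or row indices (default all).
#' @param sites site keys or column indices (default all).
#' @return the subsetted `MethylationMatrix`.
#' @export
subset_matrix <- function(x, samples = NULL, sites = NULL) {
  i <- if (is.null(samples)) seq_len(nrow(x$samples))
       else if (is.character(samples)) match(samples, x$samples$sample_id)
       else samples
  j <- if (is.null(sites)) seq_len(nrow(x$sites))
       else if (is.character(sites)) match(sites, colnames(x$pct))
       else sites
  if (anyNA(i)) stop("unknown sample id(s)")
  if (anyNA(j)) stop("unknown site key(s)")
  new_methylation_matrix(x$samples[i, , drop = FALSE],
                         x$sites[j, , drop = FALSE],
                         x$pct[i, j, drop = FALSE],
                         x$coverage[i, j, drop = FALSE],
                         x$mask[i, j, drop = FALSE])
}

## ---- clock definitions ----------------------------------------------------

#' Construct a clock definition
#'
#' A linear epigenetic clock: CpG sites with weights (days per percent
#' methylation), an intercept (days) and an age transform mapping the linear
#' score to age. `train_mean` stores per-site training-set mean methylation,
#' used to impute uncovered clock sites at prediction time.
#'
#' @param name clock name.
#' @param sites data.frame with columns `chrom`, `pos`, `weight` and
#'   optionally `train_mean` (percent; `NA` allowed).
#' @param intercept intercept in days (or on the score scale for transformed
#'   clocks).
#' @param transform a transform spec from [transform_spec()].
#' @param min_site_fraction minimum fraction of clock sites that must be
#'   covered for a prediction to be flagged valid (default 0.9).
#' @param strand_policy `"forward_only"` or `"dinucleotide_merged"` —
#'   whether the clock's methylation values are single-strand or merged
#'   across the CpG dinucleotide.
#' @return a `ClockDefinition`.
#' @export
clock_definition <- function(name, sites, intercept,
                             transform = transform_spec("identity"),
                             min_site_fraction = 0.9,
                             strand_policy = c("forward_only",
                                               "dinucleotide_merged")) {
  strand_policy <- match.arg(strand_policy)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "weight") %in% names(sites)))
  sites$chrom <- normalize_chrom(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (!"train_mean" %in% names(sites)) sites$train_mean <- NA_real_
  if (anyDuplicated(site_key(sites$chrom, sites$pos)))
    stop("duplicate clock site")
  if (!is.finite(intercept)) stop("intercept must be finite")
  if (nrow(sites) == 0 || !all(is.finite(sites$weight)))
    stop("clock weights must be finite and nonempty")
  if (all(sites$weight == 0)) stop("clock weights must not all be zero")
  sites <- sites[site_order(sites$chrom, sites$pos),
                 c("chrom", "pos", "weight", "train_mean"), drop = FALSE]
  rownames(sites) <- NULL
  structure(list(name = name, sites = sites, intercept = intercept,
                 transform = validate_transform(transform),
                 min_site_fraction = min_site_fraction,
                 strand_policy = strand_policy),
            class = "ClockDefinition")
}

#' @export
print.ClockDefinition <- function(x, ...) {
  cat(sprintf("<ClockDefinition> %s: %d CpG sites, intercept %.4g, transform %s\n",
              x$name, nrow(x$sites), x$intercept, x$transform$form))
  invisible(x)
}

#' Age transform specification
#'
#' Clocks trained on log-transformed age (or with logistic calibration)
#' convert the linear score into age through a monotone transform:
#' `identity` (age = score), `exp_linear` (age = exp(a*score + b)), or
#' `logistic` (age = c / (1 + exp(-a*score - b))).
#'
#' @param form one of "identity", "exp_linear", "logistic".
#' @param ... named numeric parameters (`a`, `b` for exp_linear; `a`, `b`,
#'   `c` for logistic).
#' @return a `TransformSpec` list.
#' @export
transform_spec <- function(form = c("identity", "exp_linear", "logistic"), ...) {
  form <- match.arg(form)
  validate_transform(structure(list(form = form, params = list(...)),
                               class = "TransformSpec"))
}

validate_transform <- function(tr) {
  needed <- switch(tr$form,
                   identity = character(0),
                   exp_linear = c("a", "b"),
                   logistic = c("a", "b", "c"),
                   stop("unknown transform form: ", tr$form))
  missing <- setdiff(needed, names(tr$params))
  if (length(missing))
    stop("transform '", tr$form, "' missing parameter(s): ",
         paste(missing, collapse = ", "))
  for (p in needed) stopifnot(is.finite(tr$params[[p]]))
  tr
}

#' Read / write clock definition files
#'
#' Clock files are TSV with comment headers (`#name=`, `#intercept=`,
#' `#transform=<form>;a=..;b=..`, `#min_site_fraction=`, `#strand_policy=`)
#' followed by columns `chrom`, `pos_1based`, `weight`, `train_mean`
#' (train_mean may be "NA"). Weights round-trip at full precision.
#'
#' @param path file path.
#' @return `read_clock_definition`: a `ClockDefinition`.
#' @export
read_clock_definition <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_hdr <- function(key, default = NULL) {
    hit <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (!length(hit)) return(default)
    sub(paste0("^#", key, "="), "", hit[1])
  }
  if (!length(body)) stop("clock file has no site rows: ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!all(c("chrom", "pos_1based", "weight") %in% cols))
    stop("clock file must have columns chrom, pos_1based, weight (missing: ",
         paste(setdiff(c("chrom", "pos_1based", "weight"), cols), collapse = ", "),
         ")")
  dt <- data.table::fread(text = paste(body, collapse = "\n"), sep = "\t",
                          header = TRUE, na.strings = "NA",
                          colClasses = list(character = "chrom"))
  sites <- data.frame(chrom = dt$chrom, pos = as.integer(dt$pos_1based),
                      weight = as.numeric(dt$weight),
                      train_mean = if ("train_mean" %in% names(dt))
                        as.numeric(dt$train_mean) else NA_real_)
  tr_str <- get_hdr("transform", "identity")
  tr_parts <- strsplit(tr_str, ";", fixed = TRUE)[[1]]
  params <- list()
  if (length(tr_parts) > 1) {
    kv <- strsplit(tr_parts[-1], "=", fixed = TRUE)
    params <- setNames(lapply(kv, function(x) as.numeric(x[2])),
                       vapply(kv, `[`, "", 1))
  }
  transform <- validate_transform(structure(
    list(form = tr_parts[1], params = params), class = "TransformSpec"))
  intercept <- get_hdr("intercept")
  if (is.null(intercept)) stop("clock file missing #intercept= header: ", path)
  clock_definition(
    name = get_hdr("name", sub("\\.(tsv|txt)$", "", basename(path))),
    sites = sites,
    intercept = as.numeric(intercept),
    transform = transform,
    min_site_fraction = as.numeric(get_hdr("min_site_fraction", "0.9")),
    strand_policy = get_hdr("strand_policy", "forward_only"))
}

#' @param clock a `ClockDefinition`.
#' @rdname read_clock_definition
#' @return `write_clock_definition`: `path`, invisibly.
#' @export
write_clock_definition <- function(clock, path) {
  tr <- clock$transform
  tr_str <- if (length(tr$params))
    paste0(tr$form, ";", paste0(names(tr$params), "=",
           vapply(tr$params, format, "", digits = 17), collapse = ";"))
  else tr$form
  hdr <- c(paste0("#name=", clock$name),
           paste0("#intercept=", format(clock$intercept, digits = 17)),
           paste0("#transform=", tr_str),
           paste0("#min_site_fraction=", format(clock$min_site_fraction, digits = 17)),
           paste0("#strand_policy=", clock$strand_policy))
  s <- clock$sites
  body <- c("chrom\tpos_1based\tweight\ttrain_mean",
            sprintf("%s\t%d\t%s\t%s", s$chrom, s$pos,
                    vapply(s$weight, format, "", digits = 17),
                    ifelse(is.na(s$train_mean), "NA",
                           vapply(s$train_mean, format, "", digits = 17))))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export clock sites as BED intervals
#'
#' Converts the 1-based inclusive site coordinates to BED's 0-based
#' half-open convention (each CpG becomes a 1-bp interval).
#' @param clock a `ClockDefinition`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_clock_bed <- function(clock, path) {
  s <- clock$sites
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", s$chrom, s$pos - 1L, s$pos,
                     site_key(s$chrom, s$pos),
                     vapply(s$weight, format, "", digits = 10)), path)
  invisible(path)
}
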
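#' Remove alignments with low mapping quality
#'
#' Keeps exactly the reads with `MAPQ >= min_mapq` (alignments with
#' `MAPQ < 30` are discarded by default), preserving order.
#'
#' @param read_set a `read_set`.
#' @param min_mapq minimum retained MAPQ (default 30).
#' @return the filtered `read_set`.
#' @export
filter_mapq <- function(read_set, min_mapq = 30L) {
  keep <- read_set$reads$mapq >= min_mapq
  .subset_read_set(read_set, keep)
}

.subset_read_set <- function(read_set, keep) {
  reads <- read_set$reads[keep]
  devs <- read_set$devs[read_set$devs$rid %in% reads$rid]
  structure(list(reads = reads, devs = devs), class = "read_set")
}

#' Deduplicate overlapping reads within each sample
#'
#' Ultra-low-coverage allele-frequency estimation assumes each sample
#' contributes at most one allele (read) per genome position; overlapping
#' read pairs violate that.  This filter keeps, within each sample and
#' chromosome, a maximal set of pairwise non-overlapping reads so that
#' every position receives at most one read per sample.  Reads from
#' different samples never affect each other.
#'
#' Which overlapping read survives is resolved by a deterministic greedy
#' sweep: reads are sorted by (start, end, read id) and a read is kept iff
#' it does not overlap the previously kept read.  The operation is
#' idempotent and independent of input order.
#'
#' @param read_set a `read_set`.
#' @return the filtered `read_set`.
#' @export
deduplicate_overlaps <- function(read_set) {
  r <- read_set$reads
  if (nrow(r) == 0L) return(read_set)
  ord <- order(r$sample_id, r$chrom, r$start, r$end, r$rid)
  s <- r[ord]
  grp <- paste(s$sample_id, s$chrom, sep = "\r")
  keep_sorted <- .greedy_sweep(s$start, s$end, grp)
  kept_rids <- s$rid[keep_sorted]
  .subset_read_set(read_set, r$rid %in% kept_rids)
}

# greedy non-overlap selection within runs of identical `grp`
.greedy_sweep <- function(start, end, grp) {
  n <- length(start)
  keep <- logical(n)
  last_end <- -1L
  last_grp <- ""
  for (i in seq_len(n)) {
    if (grp[i] != last_grp || start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- end[i]
      last_grp <- grp[i]
    }
  }
  keep
}

#' Expected sequencing depth from read counts
#'
#' Depth (x) contributed by `n_read_pairs` paired-end reads of `read_len`
#' bases each over a genome of `genome_len` bp:
#' `n_read_pairs * 2 * read_len / genome_len`.
#'
#' @param n_read_pairs,read_len,genome_len positive numbers.
#' @examples
#' expected_depth(3.6e6, 75, 3.099e9)  # ~0.17x
#' @export
expected_depth <- function(n_read_pairs, read_len, genome_len) {
  .check_positive(n_read_pairs, "n_read_pairs")
  .check_positive(read_len, "read_len")
  .check_positive(genome_len, "genome_len")
  n_read_pairs * 2 * read_len / genome_len
}

#' Expected number of samples contributing two reads at a position
#'
#' With a fraction `per_sample_depth2_fraction` of each sample's positions
#' covered by two overlapping reads, a cohort of `n_samples` contributes on
#' average `n_samples * per_sample_depth2_fraction` double-read samples at
#' any position.
#'
#' @param n_samples cohort size.
#' @param per_sample_depth2_fraction fraction in `[0, 1]`.
#' @examples
#' expected_two_read_samples(2683, 0.0175)  # ~47
#' @export
expected_two_read_samples <- function(n_samples,
                                      per_sample_depth2_fraction) {
  .check_prob(per_sample_depth2_fraction, "per_sample_depth2_fraction")
  n_samples * per_sample_depth2_fraction
}

# list of per-chromosome coverage Rle from a reads table
.coverage_rle <- function(reads, genome) {
  unknown <- setdiff(unique(reads$chrom), genome$chroms$chrom)
  if (length(unknown))
    stop("reads reference unknown chromosomes: ",
         paste(unknown, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(genome$chroms))) {
    ch <- genome$chroms$chrom[i]
    r <- reads[reads$chrom == ch]
    out[[ch]] <- IRanges::coverage(
      IRanges::IRanges(r$start, r$end), width = genome$chroms$length[i])
  }
  out
}

# depth-value tabulation of an Rle coverage vector
.depth_table <- function(rle) {
  v <- S4Vectors::runValue(rle)
  l <- S4Vectors::runLength(rle)
  tapply(as.numeric(l), v, sum)
}

#' Coverage and depth accounting for a read set
#'
#' Exact per-position accounting (no sampling): per-sample genome coverage
#' fraction, mean depth, and fraction of positions at each depth `1..max_k`;
#' aggregate (pooled) coverage fraction and total depth; per-chromosome mean
#' pooled depth; and a pooled depth histogram with an overflow bin at
#' `> max_k`.
#'
#' @param read_set a `read_set`.
#' @param genome a `toy_genome`.
#' @param max_k largest exact depth bin (default 5).
#' @param per_sample compute per-sample summaries (default TRUE).
#' @return a `coverage_summary`: list with `per_sample` (data.table),
#'   `aggregate` (list: `coverage`, `mean_depth`), `per_chrom`
#'   (data.table: `chrom`, `mean_depth`), `depth_hist` (data.table:
#'   `depth`, `positions`; depth `max_k + 1` is the overflow bin).
#' @export
coverage_summary <- function(read_set, genome, max_k = 5L,
                             per_sample = TRUE) {
  reads <- read_set$reads
  L <- genome_length(genome)
  cov <- .coverage_rle(reads, genome)

  chrom_depth <- data.table(
    chrom = genome$chroms$chrom,
    mean_depth = vapply(genome$chroms$chrom, function(ch)
      sum(as.numeric(S4Vectors::runValue(cov[[ch]]) *
                       S4Vectors::runLength(cov[[ch]]))) /
        genome$chroms$length[genome$chroms$chrom == ch],
      numeric(1))
  )

  hist_counts <- numeric(max_k + 2L)  # depths 0..max_k plus overflow
  covered <- 0; total_bases <- 0
  for (ch in names(cov)) {
    tab <- .depth_table(cov[[ch]])
    d <- as.numeric(names(tab))
    covered <- covered + sum(tab[d > 0])
    total_bases <- total_bases + sum(d * tab)
    bin <- pmin(d, max_k + 1) + 1
    for (j in seq_along(tab)) {
      hist_counts[bin[j]] <- hist_counts[bin[j]] + tab[j]
    }
  }

  per_sample_dt <- NULL
  if (per_sample && nrow(reads)) {
    ids <- sort(unique(reads$sample_id))
    rows <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      sc <- .coverage_rle(reads[reads$sample_id == ids[k]], genome)
      cnt <- numeric(max_k + 2L)
      cov_s <- 0; bases_s <- 0
      for (ch in names(sc)) {
        tab <- .depth_table(sc[[ch]])
        d <- as.numeric(names(tab))
        cov_s <- cov_s + sum(tab[d > 0])
        bases_s <- bases_s + sum(d * tab)
        bin <- pmin(d, max_k + 1) + 1
        for (j in seq_along(tab)) cnt[bin[j]] <- cnt[bin[j]] + tab[j]
      }
      row <- data.table(sample_id = ids[k], coverage = cov_s / L,
                        mean_depth = bases_s / L)
      for (kk in seq_len(max_k)) {
        row[[paste0("frac_depth", kk)]] <- cnt[kk + 1L] / L
      }
      rows[[k]] <- row
    }
    per_sample_dt <- rbindlist(rows)
  }

  structure(list(
    per_sample = per_sample_dt,
    aggregate = list(coverage = covered / L, mean_depth = total_bases / L),
    per_chrom = chrom_depth,
    depth_hist = data.table(depth = 0:(max_k + 1L), positions = hist_counts)
  ), class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("coverage_summary: aggregate coverage %.2f%%, depth %.3fx\n",
              100 * x$aggregate$coverage, x$aggregate$mean_depth))
  invisible(x)
}

#' Per-sample maximum depth at any position
#'
#' Verification helper for the one-read-per-sample-per-position guarantee
#' of [deduplicate_overlaps()].
#'
#' @param read_set a `read_set`.
#' @param genome a `toy_genome`.
#' @return named integer vector: maximum per-position depth per sample.
#' @export
max_depth_per_sample <- function(read_set, genome) {
  ids <- unique(read_set$reads$sample_id)
  vapply(setNames(ids, ids), function(id) {
    cov <- .coverage_rle(read_set$reads[read_set$reads$sample_id == id],
                         genome)
    max(vapply(cov, function(r) max(c(0L, S4Vectors::runValue(r))),
               integer(1)))
  }, integer(1))
}
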
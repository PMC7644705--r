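#' Pooled pileup over all samples' filtered reads
#'
#' Aggregates every sample's reads into one pool (the cohort is treated as
#' a single meta-sample) and counts, per genome position, the reads
#' supporting each base, split by strand.  After preprocessing, every read
#' at a position comes from a different sample, so the pooled alternate
#' read fraction estimates the population allele frequency.
#'
#' Columns are materialised only where at least one non-reference base is
#' observed, or at the requested `sites`: positions covered exclusively by
#' reference bases carry no variant evidence.  Read bases outside
#' {A,C,G,T} are skipped and counted in the `skipped_bases` attribute.
#'
#' @param read_set a post-preprocessing `read_set`.
#' @param genome a `toy_genome`.
#' @param sites optional data.frame (`chrom`, `pos`) restricting the
#'   pileup to those positions (columns with `n = 0` are then included).
#' @return a `pileup_cols` data.table: `chrom`, `pos`, `ref`, `n`,
#'   `n_fwd`, `n_rev`, per-base counts `A_fwd`, `A_rev`, ..., `T_rev`,
#'   and `n_samples` (distinct samples contributing reads at the
#'   position).
#' @export
pileup <- function(read_set, genome, sites = NULL) {
  reads <- read_set$reads
  dv <- merge(read_set$devs,
              reads[, c("rid", "chrom", "strand", "sample_id")],
              by = "rid")
  skipped <- sum(!dv$base %in% BASES)
  dv <- dv[dv$base %in% BASES]

  if (is.null(sites)) {
    cand <- unique(dv[, c("chrom", "pos")])
  } else {
    cand <- unique(as.data.table(sites)[, c("chrom", "pos")])
  }
  setkey(cand, chrom, pos)
  if (nrow(cand) == 0L) {
    out <- .empty_pileup()
    setattr(out, "skipped_bases", skipped)
    return(out)
  }

  fwd <- .coverage_rle(reads[reads$strand == "+"], genome)
  rev <- .coverage_rle(reads[reads$strand == "-"], genome)
  n_fwd <- integer(nrow(cand)); n_rev <- integer(nrow(cand))
  for (ch in unique(cand$chrom)) {
    i <- which(cand$chrom == ch)
    n_fwd[i] <- as.integer(fwd[[ch]][cand$pos[i]])
    n_rev[i] <- as.integer(rev[[ch]][cand$pos[i]])
  }

  cols <- data.table(chrom = cand$chrom, pos = cand$pos,
                     ref = .ref_base_at(genome, cand$chrom, cand$pos),
                     n = n_fwd + n_rev, n_fwd = n_fwd, n_rev = n_rev)
  for (b in BASES) for (s in c("fwd", "rev")) {
    cols[[paste(b, s, sep = "_")]] <- 0L
  }
  if (nrow(dv)) {
    dvc <- dv[, list(count = .N),
              by = c("chrom", "pos", "base", "strand")]
    key <- paste(cols$chrom, cols$pos)
    for (b in BASES) for (s in c("+", "-")) {
      sub <- dvc[dvc$base == b & dvc$strand == s]
      if (!nrow(sub)) next
      j <- match(paste(sub$chrom, sub$pos), key)
      colname <- paste(b, if (s == "+") "fwd" else "rev", sep = "_")
      ok <- !is.na(j)
      cols[[colname]][j[ok]] <- sub$count[ok]
    }
  }
  # reference counts on each strand = strand totals minus deviant bases
  dev_f <- rowSums(as.matrix(cols[, paste0(BASES, "_fwd"), with = FALSE]))
  dev_r <- rowSums(as.matrix(cols[, paste0(BASES, "_rev"), with = FALSE]))
  ri <- match(cols$ref, BASES)
  for (b in seq_along(BASES)) {
    i <- which(ri == b)
    cols[[paste0(BASES[b], "_fwd")]][i] <- cols$n_fwd[i] - dev_f[i]
    cols[[paste0(BASES[b], "_rev")]][i] <- cols$n_rev[i] - dev_r[i]
  }
  cols[["n_samples"]] <- .distinct_samples_at(reads, cols)
  setattr(cols, "skipped_bases", skipped)
  setattr(cols, "class", c("pileup_cols", class(cols)))
  cols[]
}

.empty_pileup <- function() {
  out <- data.table(chrom = character(), pos = integer(),
                    ref = character(), n = integer(),
                    n_fwd = integer(), n_rev = integer())
  for (b in BASES) for (s in c("fwd", "rev"))
    out[[paste(b, s, sep = "_")]] <- integer()
  out[["n_samples"]] <- integer()
  setattr(out, "class", c("pileup_cols", class(out)))
  out
}

.distinct_samples_at <- function(reads, cols) {
  ns <- integer(nrow(cols))
  for (ch in unique(cols$chrom)) {
    i <- which(cols$chrom == ch)
    r <- which(reads$chrom == ch)
    if (!length(r)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(cols$pos[i], cols$pos[i]),
      IRanges::IRanges(reads$start[r], reads$end[r]))
    if (!length(ov)) next
    hits <- data.table(q = S4Vectors::queryHits(ov),
                       s = reads$sample_id[r[S4Vectors::subjectHits(ov)]])
    cnt <- hits[, list(k = length(unique(s))), by = "q"]
    ns[i[cnt$q]] <- cnt$k
  }
  ns
}

#' Call variants from pooled pileup columns with a binomial error model
#'
#' For each non-reference base `b` with pooled count `k` out of depth `n`,
#' the sequencing-error null is `X ~ Binomial(n, error_rate / 3)` (errors
#' substitute uniformly to the three non-reference bases).  A variant is
#' emitted iff the tail probability `P(X >= k)` is at most `alpha_site`.
#' The allele frequency estimate is `k / n`.  Calls with `k < min_alt`
#' are flagged `weak_evidence`; [strand_bias_filter()] adds
#' `strand_bias`; `PASS` means no flag.  Several alternate alleles may be
#' called at one site.
#'
#' `alpha_site` defaults to a Bonferroni bound `0.05 / genome_len` over
#' genome positions.
#'
#' @param columns a `pileup_cols` table (or a single column for
#'   [call_site()]).
#' @param error_rate per-base sequencing error rate in `[0, 0.5)`.
#' @param alpha_site per-site significance threshold; default
#'   `0.05 / genome_len`.
#' @param genome_len genome length used for the default `alpha_site`.
#' @param min_alt minimum alternate read count below which a call is
#'   flagged `weak_evidence` (default 3).
#' @param strand_p,strand_frac parameters of [strand_bias_filter()].
#' @return a `variant_calls` data.table: `chrom`, `pos`, `ref`, `alt`,
#'   `k`, `n`, `af`, `p_value`, `filter`, plus per-strand ref/alt counts.
#' @export
call_variants <- function(columns, error_rate = 0.003,
                          alpha_site = NULL, genome_len = NULL,
                          min_alt = 3L, strand_p = 1e-3,
                          strand_frac = 0.9) {
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (is.null(alpha_site)) {
    if (is.null(genome_len))
      stop("supply alpha_site or genome_len for the Bonferroni default")
    alpha_site <- 0.05 / genome_len
  }
  cols <- as.data.table(columns)
  cols <- cols[cols$n >= 1L]
  if (nrow(cols) == 0L) return(.empty_calls())

  long <- vector("list", 3L)
  z <- 0L
  for (b in BASES) {
    sub <- cols[cols$ref != b]
    if (!nrow(sub)) next
    kf <- sub[[paste0(b, "_fwd")]]
    kr <- sub[[paste0(b, "_rev")]]
    k <- kf + kr
    keep <- which(k >= 1L)
    if (!length(keep)) next
    z <- z + 1L
    ri <- match(sub$ref[keep], BASES)
    long[[z]] <- data.table(
      chrom = sub$chrom[keep], pos = sub$pos[keep], ref = sub$ref[keep],
      alt = b, k = k[keep], n = sub$n[keep],
      alt_fwd = kf[keep], alt_rev = kr[keep],
      ref_fwd = as.integer(as.matrix(
        sub[keep, paste0(BASES, "_fwd"), with = FALSE])[cbind(seq_along(keep), ri)]),
      ref_rev = as.integer(as.matrix(
        sub[keep, paste0(BASES, "_rev"), with = FALSE])[cbind(seq_along(keep), ri)])
    )
  }
  if (z == 0L) return(.empty_calls())
  calls <- rbindlist(long[seq_len(z)])
  calls[, "p_value" := pbinom(calls$k - 1L, calls$n, error_rate / 3,
                              lower.tail = FALSE)]
  calls <- calls[calls$p_value <= alpha_site]
  if (nrow(calls) == 0L) return(.empty_calls())
  calls[, "af" := calls$k / calls$n]
  calls[, "weak_evidence" := calls$k < min_alt]
  calls <- strand_bias_filter(calls, p_threshold = strand_p,
                              frac_threshold = strand_frac)
  calls[, "filter" := .filter_string(calls)]
  setorderv(calls, c("chrom", "pos", "alt"))
  setcolorder(calls, c("chrom", "pos", "ref", "alt", "k", "n", "af",
                       "p_value", "filter"))
  setattr(calls, "class", c("variant_calls", class(calls)))
  calls[]
}

.filter_string <- function(calls) {
  f <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    flags <- c(if (calls$weak_evidence[i]) "weak_evidence",
               if (calls$strand_bias[i]) "strand_bias")
    f[i] <- if (length(flags)) paste(flags, collapse = ";") else "PASS"
  }
  f
}

.empty_calls <- function() {
  out <- data.table(chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    k = integer(), n = integer(), af = numeric(),
                    p_value = numeric(), filter = character(),
                    alt_fwd = integer(), alt_rev = integer(),
                    ref_fwd = integer(), ref_rev = integer(),
                    weak_evidence = logical(), strand_bias = logical())
  setattr(out, "class", c("variant_calls", class(out)))
  out
}

#' @rdname call_variants
#' @param column one pileup column (single-row `pileup_cols`).
#' @param ... passed to [call_variants()].
#' @export
call_site <- function(column, ...) {
  stopifnot(nrow(column) == 1L, column$n >= 1L)
  call_variants(column, ...)
}

#' Flag calls with strand-biased alternate support
#'
#' A call is flagged `strand_bias` iff the two-sided Fisher exact test on
#' the 2x2 table `[[ref_fwd, ref_rev], [alt_fwd, alt_rev]]` has
#' `p < p_threshold` *and* at least `frac_threshold` of the alternate
#' reads fall on one strand.
#'
#' @param calls a `variant_calls` table carrying per-strand counts.
#' @param p_threshold Fisher-test significance threshold (default 1e-3).
#' @param frac_threshold one-strand alternate fraction (default 0.9).
#' @return `calls` with a logical `strand_bias` column updated.
#' @export
strand_bias_filter <- function(calls, p_threshold = 1e-3,
                               frac_threshold = 0.9) {
  n <- nrow(calls)
  sb <- logical(n)
  if (n) {
    one_strand <- pmax(calls$alt_fwd, calls$alt_rev) /
      pmax(1L, calls$alt_fwd + calls$alt_rev)
    for (i in seq_len(n)) {
      if (one_strand[i] < frac_threshold) next
      p <- fisher.test(matrix(c(calls$ref_fwd[i], calls$ref_rev[i],
                                calls$alt_fwd[i], calls$alt_rev[i]),
                              2, 2, byrow = TRUE))$p.value
      sb[i] <- p < p_threshold
    }
  }
  calls[, "strand_bias" := sb]
  calls
}
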
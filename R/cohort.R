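#' Simulate an NIPT cohort (mother + fetus haplotypes per sample)
#'
#' For each pregnancy, maternal and paternal genotypes are drawn
#' independently from the chosen population's allele frequencies (as phased
#' haplotypes), and the fetal genotype is formed from one maternal and one
#' paternal gamete per site.  Fathers are drawn and discarded; only the
#' mother and fetus persist, since only their DNA appears in plasma.
#' Mothers carry no Y; a male fetus carries one maternal X and one Y, a
#' female fetus one maternal and one paternal X.
#'
#' The fetal fraction (the proportion of plasma DNA that is fetal) is drawn
#' per sample from `fetal_fraction_dist`; the default draws uniformly from
#' 8-10%, the range typical of first-trimester NIPT samples.
#'
#' @param af_table an [simulate_population_afs()] table.
#' @param population population label whose frequencies the parents follow.
#' @param n_samples number of pregnancies.
#' @param fetal_fraction_dist function of `n` returning `n` fetal fractions
#'   in `[0, 1]`.
#' @param p_male probability that the fetus is male.
#' @param depth_dist function of `n` returning per-sample target sequencing
#'   depths (x); default constant 0.17.
#' @param seed integer master seed; per-sample randomness is derived from it
#'   by counter.
#' @return a `nipt_cohort`: list of per-sample specs, each with
#'   `sample_id`, `fetal_fraction`, `fetal_sex`, `target_depth`, a
#'   haplotype matrix `hap` (sites x 4: maternal copies `m1`, `m2`, fetal
#'   copies `f1` = maternal gamete, `f2` = paternal gamete, `NA` where the
#'   copy does not exist), and dosage vectors `maternal_dosage`,
#'   `fetal_dosage`.  The attribute `sites` holds the site table.
#' @export
simulate_nipt_cohort <- function(af_table, population, n_samples,
                                 fetal_fraction_dist = function(n)
                                   runif(n, 0.08, 0.10),
                                 p_male = 0.5,
                                 depth_dist = function(n) rep(0.17, n),
                                 seed = 1L) {
  stopifnot(n_samples >= 1)
  .check_prob(p_male, "p_male")
  p <- .af_column(af_table, population)
  n_sites <- nrow(af_table)
  is_x <- af_table$chrom == "chrX"

  set.seed(seed)
  ff <- fetal_fraction_dist(n_samples)
  .check_prob(ff, "fetal_fraction")
  sex <- ifelse(runif(n_samples) < p_male, "male", "female")
  depth <- depth_dist(n_samples)

  seeds <- derive_seeds(seed, n_samples, stream = 1L)
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    set.seed(seeds[i])
    m1 <- rbinom(n_sites, 1L, p)
    m2 <- rbinom(n_sites, 1L, p)
    # father: two autosomal/X haplotypes; only one X copy is real but
    # drawing both is harmless since X transmission picks the single copy
    fa1 <- rbinom(n_sites, 1L, p)
    fa2 <- rbinom(n_sites, 1L, p)
    # gametes: one maternal and one paternal allele per site
    f1 <- ifelse(runif(n_sites) < 0.5, m1, m2)            # maternal gamete
    f2 <- ifelse(runif(n_sites) < 0.5, fa1, fa2)          # paternal gamete
    male <- sex[i] == "male"
    if (male) f2[is_x] <- NA_integer_  # male fetus: single (maternal) X
    hap <- cbind(m1 = m1, m2 = m2, f1 = f1, f2 = f2)
    samples[[i]] <- list(
      sample_id = sprintf("S%04d", i),
      fetal_fraction = ff[i],
      fetal_sex = if (male) "male" else "female",
      target_depth = depth[i],
      hap = hap,
      maternal_dosage = m1 + m2,
      fetal_dosage = f1 + ifelse(is.na(f2), 0L, f2)
    )
  }
  structure(samples, sites = af_table[, c("chrom", "pos", "ref", "alt")],
            class = "nipt_cohort")
}

#' @export
print.nipt_cohort <- function(x, ...) {
  cat(sprintf(
    "nipt_cohort: %d samples, %d truth sites, %d male fetuses, mean ff %.3f\n",
    length(x), nrow(attr(x, "sites")),
    sum(vapply(x, function(s) s$fetal_sex == "male", logical(1))),
    mean(vapply(x, function(s) s$fetal_fraction, numeric(1)))))
  invisible(x)
}

#' Cohort metadata as a table
#' @param cohort a `nipt_cohort`.
#' @return data.table with `sample_id`, `fetal_fraction`, `fetal_sex`,
#'   `target_depth`.
#' @export
cohort_metadata <- function(cohort) {
  rbindlist(lapply(cohort, function(s)
    data.table(sample_id = s$sample_id,
               fetal_fraction = s$fetal_fraction,
               fetal_sex = s$fetal_sex,
               target_depth = s$target_depth)))
}

# Enumerate the chromosome copies present in one sample's plasma, with
# sampling weights length x dosage: each maternal copy carries weight
# (1 - ff), each fetal copy weight ff.  `hap_col` names the haplotype
# column supplying alleles for reads drawn from that copy (NA on Y, which
# carries no variant sites).
.plasma_copies <- function(sample, genome) {
  ff <- sample$fetal_fraction
  male <- sample$fetal_sex == "male"
  out <- list()
  for (i in seq_len(nrow(genome$chroms))) {
    ch <- genome$chroms$chrom[i]
    len <- as.numeric(genome$chroms$length[i])
    cls <- genome$chroms$class[i]
    if (cls %in% c("autosome", "X")) {
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, hap_col = c("m1", "m2"), weight = (1 - ff) * len)
      fet_cols <- if (cls == "X" && male) "f1" else c("f1", "f2")
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, hap_col = fet_cols, weight = ff * len)
    } else if (cls == "Y" && male) {
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, hap_col = NA_character_, weight = ff * len)
    }
  }
  rbindlist(out)
}

#' Simulate aligned cfDNA read pairs for one sample
#'
#' Draws paired-end fragments from the maternal/fetal plasma mixture: a
#' chromosome copy is chosen with probability proportional to its length
#' times its mixture weight ((1 - ff) per maternal copy, ff per fetal
#' copy), the fragment midpoint is uniform along the copy, and the fragment
#' length follows a truncated normal insert-size distribution (default
#' Normal(166, 40) truncated to `[read_len + 1, 500]`, matching the modal
#' cfDNA fragment length of about 166 bp).  Two mates of `read_len` bases
#' are taken from the fragment ends.  At every position the emitted base is
#' the source haplotype's allele, substituted uniformly to one of the other
#' three bases with probability `error_rate`.  MAPQ is 60 except for reads
#' falling in designated low-mappability intervals.
#'
#' Reads are returned pre-aligned (the simulator emits alignments, not raw
#' reads): base calls are stored sparsely as deviations from the reference,
#' which is lossless because every non-deviant base equals the reference.
#'
#' @param sample one element of a [simulate_nipt_cohort()].
#' @param genome a [toy_genome()].
#' @param af_table the truth site table the cohort was simulated from.
#' @param read_len read length in bp (default 75).
#' @param insert_mean,insert_sd,insert_max insert-size model.
#' @param error_rate per-base substitution error probability in `[0, 0.5)`.
#' @param low_map optional data.frame (`chrom`, `start`, `end`) of
#'   low-mappability intervals.
#' @param low_mapq MAPQ assigned to affected reads (must be < 30).
#' @param low_map_frac fraction of reads in `low_map` intervals that
#'   receive `low_mapq`.
#' @param n_pairs number of read pairs; default derived from the sample's
#'   target depth as `depth * genome_length / (2 * read_len)`.
#' @param seed integer seed.
#' @return a `read_set`: list with `reads` (data.table: `rid`, `qname`,
#'   `mate`, `sample_id`, `chrom`, `start`, `end`, `strand`, `mapq`) and
#'   `devs` (data.table: `rid`, `pos`, `base` — positions where the read
#'   base differs from the reference).
#' @export
simulate_reads <- function(sample, genome, af_table,
                           read_len = 75L, insert_mean = 166,
                           insert_sd = 40, insert_max = 500,
                           error_rate = 0.003,
                           low_map = NULL, low_mapq = 10L,
                           low_map_frac = 1.0,
                           n_pairs = NULL, seed = 1L) {
  stopifnot(read_len >= 1)
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (nrow(genome$chroms) == 0L) stop("empty genome")
  if (is.null(n_pairs)) {
    n_pairs <- round(sample$target_depth * genome_length(genome) /
                       (2 * read_len))
  }
  set.seed(seed)
  copies <- .plasma_copies(sample, genome)
  chrom_len <- setNames(as.numeric(genome$chroms$length),
                        genome$chroms$chrom)
  empty <- .empty_read_set()
  if (n_pairs == 0L || nrow(copies) == 0L || sum(copies$weight) == 0)
    return(empty)

  ci <- sample.int(nrow(copies), n_pairs, replace = TRUE,
                   prob = copies$weight)
  chrom <- copies$chrom[ci]
  hap_col <- copies$hap_col[ci]
  L <- chrom_len[chrom]
  flen <- round(rtruncnorm(n_pairs, insert_mean, insert_sd,
                           read_len + 1, insert_max))
  flen <- pmin(flen, L)  # a toy chromosome may be shorter than the insert
  mid <- runif(n_pairs, 0.5, L + 0.5)
  fstart <- pmax(1, pmin(L - flen + 1, round(mid - flen / 2)))
  fend <- fstart + flen - 1

  reads <- data.table(
    rid = seq_len(2L * n_pairs),
    qname = rep(sprintf("%s:%07d", sample$sample_id, seq_len(n_pairs)), 2L),
    mate = rep(c(1L, 2L), each = n_pairs),
    sample_id = sample$sample_id,
    chrom = rep(chrom, 2L),
    start = c(as.integer(fstart), as.integer(fend - read_len + 1)),
    end = c(as.integer(fstart + read_len - 1), as.integer(fend)),
    strand = rep(c("+", "-"), each = n_pairs),
    mapq = 60L,
    hap_col = rep(hap_col, 2L)
  )

  if (!is.null(low_map) && nrow(low_map)) {
    hit <- .overlaps_any(reads, as.data.table(low_map))
    flip <- which(hit & runif(nrow(reads)) < low_map_frac)
    if (length(flip)) reads[flip, "mapq" := as.integer(low_mapq)]
  }

  devs <- .read_deviations(reads, genome, af_table, sample$hap,
                           read_len, error_rate)
  reads[, "hap_col" := NULL]
  structure(list(reads = reads, devs = devs), class = "read_set")
}

.empty_read_set <- function() {
  structure(list(
    reads = data.table(rid = integer(), qname = character(),
                       mate = integer(), sample_id = character(),
                       chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       mapq = integer()),
    devs = data.table(rid = integer(), pos = integer(), base = character())
  ), class = "read_set")
}

# Positions where read bases differ from the reference: truth-site alleles
# carried by the source haplotype, plus uniform sequencing errors.
.read_deviations <- function(reads, genome, af_table, hap,
                             read_len, error_rate) {
  hits <- .overlap_site_hits(reads, af_table)
  cand <- if (nrow(hits)) {
    allele <- hap[cbind(hits$site_idx, match(hits$hap_col, colnames(hap)))]
    keep <- !is.na(allele) & allele == 1L
    data.table(rid = hits$rid[keep], pos = hits$pos[keep],
               src = af_table$alt[hits$site_idx[keep]],
               ref = af_table$ref[hits$site_idx[keep]])
  } else data.table(rid = integer(), pos = integer(),
                    src = character(), ref = character())

  n_err <- rbinom(nrow(reads), read_len, error_rate)
  err <- if (sum(n_err)) {
    e_rid <- rep(reads$rid, n_err)
    e_pos <- rep(reads$start, n_err) +
      sample.int(read_len, sum(n_err), replace = TRUE) - 1L
    unique(data.table(rid = e_rid, pos = e_pos))
  } else data.table(rid = integer(), pos = integer())
  err[, "is_err" := TRUE]

  all <- merge(cand, err, by = c("rid", "pos"), all = TRUE)
  if (nrow(all) == 0L)
    return(data.table(rid = integer(), pos = integer(), base = character()))
  need_ref <- which(is.na(all$src))
  if (length(need_ref)) {
    ch <- reads$chrom[match(all$rid[need_ref], reads$rid)]
    rb <- .ref_base_at(genome, ch, all$pos[need_ref])
    all[need_ref, c("src", "ref") := list(rb, rb)]
  }
  all[, "final" := all$src]
  ei <- which(!is.na(all$is_err))
  if (length(ei)) all[ei, "final" := .substitute_base(all$src[ei])]
  out <- all[all$final != all$ref, c("rid", "pos", "final")]
  setnames(out, "final", "base")
  setkey(out, rid, pos)
  out[]
}

# (rid, site_idx, pos, hap_col) for every read x truth-site overlap
.overlap_site_hits <- function(reads, af_table) {
  out <- vector("list", 0L)
  for (ch in unique(reads$chrom)) {
    s_idx <- which(af_table$chrom == ch)
    if (!length(s_idx)) next
    r <- which(reads$chrom == ch)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(af_table$pos[s_idx], af_table$pos[s_idx]),
      IRanges::IRanges(reads$start[r], reads$end[r]))
    if (!length(ov)) next
    si <- s_idx[S4Vectors::queryHits(ov)]
    ri <- r[S4Vectors::subjectHits(ov)]
    out[[length(out) + 1L]] <- data.table(
      rid = reads$rid[ri], site_idx = si, pos = af_table$pos[si],
      hap_col = reads$hap_col[ri])
  }
  if (!length(out)) return(data.table(rid = integer(), site_idx = integer(),
                                      pos = integer(),
                                      hap_col = character()))
  rbindlist(out)
}

# does each read overlap any interval in `intervals` (chrom, start, end)?
.overlaps_any <- function(reads, intervals) {
  hit <- logical(nrow(reads))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    r <- which(reads$chrom == ch)
    if (!length(r)) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(reads$start[r], reads$end[r]),
      IRanges::IRanges(iv$start, iv$end))
    hit[r] <- ov
  }
  hit
}

#' Simulate reads for every sample of a cohort
#'
#' Loops [simulate_reads()] over the cohort with per-sample seeds derived
#' from the master seed, and concatenates the results into one pooled
#' `read_set`.
#'
#' @inheritParams simulate_reads
#' @param cohort a `nipt_cohort`.
#' @param ... passed through to [simulate_reads()].
#' @param seed master seed.
#' @return a pooled `read_set` with globally unique `rid`.
#' @export
simulate_cohort_reads <- function(cohort, genome, af_table, ...,
                                  seed = 1L) {
  seeds <- derive_seeds(seed, length(cohort), stream = 2L)
  sets <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sets[[i]] <- simulate_reads(cohort[[i]], genome, af_table, ...,
                                seed = seeds[i])
  }
  combine_read_sets(sets)
}

#' Concatenate read sets, reindexing read ids
#' @param sets list of `read_set` objects.
#' @export
combine_read_sets <- function(sets) {
  offset <- 0L
  for (i in seq_along(sets)) {
    sets[[i]]$reads <- copy(sets[[i]]$reads)[, "rid" := rid + offset]
    sets[[i]]$devs <- copy(sets[[i]]$devs)[, "rid" := rid + offset]
    offset <- offset + nrow(sets[[i]]$reads)
  }
  structure(list(
    reads = rbindlist(lapply(sets, `[[`, "reads")),
    devs = rbindlist(lapply(sets, `[[`, "devs"))
  ), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads (%d samples), %d non-reference bases\n",
              nrow(x$reads), length(unique(x$reads$sample_id)),
              nrow(x$devs)))
  invisible(x)
}
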
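test_that("pileup counts bases and strands at a position", {
  g <- toy_genome(1000, 0, 0, seed = 1)
  pos <- 500L
  ref <- substring(g$sequence$chr1, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  rs <- make_read_set(
    data.table(sample_id = c("S1", "S2", "S3"), chrom = "chr1",
               start = c(450L, 460L, 470L), end = c(524L, 534L, 544L),
               strand = c("+", "+", "-")),
    devs = data.table(rid = 3L, pos = pos, base = alt))
  p <- pileup(rs, g)
  expect_equal(nrow(p), 1)
  expect_equal(p$n, 3L)
  expect_equal(p$n_samples, 3L)
  expect_equal(p[[paste0(ref, "_fwd")]], 2L)  # two reference bases, fwd
  expect_equal(p[[paste0(alt, "_rev")]], 1L)  # one alternate, rev strand
  # base counts always sum to depth
  base_cols <- as.matrix(p[, paste(rep(c("A", "C", "G", "T"), each = 2),
                                   c("fwd", "rev"), sep = "_"),
                           with = FALSE])
  expect_equal(sum(base_cols), p$n)
  # requested sites materialise even without variant evidence
  p2 <- pileup(rs, g, sites = data.frame(chrom = "chr1",
                                         pos = c(pos, 10L)))
  expect_equal(p2$n[p2$pos == 10L], 0L)
})

test_that("pooled pileup equals the sum of per-sample pileups", {
  s <- tiny_sim(n_samples = 6, depth = 0.8)
  flt <- deduplicate_overlaps(filter_mapq(s$reads))
  pooled <- pileup(flt, s$genome)
  ids <- unique(flt$reads$sample_id)
  per <- lapply(ids, function(id) {
    keep <- flt$reads$sample_id == id
    sub <- structure(list(reads = flt$reads[keep],
                          devs = flt$devs[flt$devs$rid %in%
                                            flt$reads$rid[keep]]),
                     class = "read_set")
    pileup(sub, s$genome, sites = pooled[, .(chrom, pos)])
  })
  for (col in c("n", "A_fwd", "C_rev", "G_fwd", "T_rev")) {
    expect_equal(pooled[[col]],
                 Reduce(`+`, lapply(per, `[[`, col)))
  }
  # after preprocessing every read at a position is a distinct sample
  expect_equal(pooled$n_samples, pooled$n)
})

test_that("the binomial tail decides calls at the stated thresholds", {
  g <- toy_genome(1000, 0, 0, seed = 2)
  mk_col <- function(n, k, pos = 100L) {
    ref <- substring(g$sequence$chr1, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    reads <- data.table(sample_id = sprintf("S%d", 1:n), chrom = "chr1",
                        start = pos - 10L, end = pos + 64L)
    devs <- data.table(rid = seq_len(k), pos = pos, base = alt)
    pileup(make_read_set(reads, devs), g)
  }
  # n=300, k=1: P(X >= 1) = 1 - 0.999^300 ~ 0.259 -> no call at 1e-8
  col <- mk_col(300, 1)
  no_call <- call_site(col, alpha_site = 1e-8)
  expect_equal(nrow(no_call), 0)
  p_closed <- 1 - (1 - 0.003 / 3)^300
  full <- call_site(col, alpha_site = 1)
  expect_equal(full$p_value, p_closed, tolerance = 1e-12)
  # n=364, k=40: overwhelming evidence; AF = 40/364
  strong <- call_site(mk_col(364, 40), alpha_site = 1e-8)
  expect_equal(nrow(strong), 1)
  expect_lt(strong$p_value, 1e-50)
  expect_equal(strong$af, 40 / 364)
  expect_equal(strong$filter, "PASS")
  # k below min_alt is emitted but flagged
  weak <- call_site(mk_col(400, 2), alpha_site = 0.1)
  expect_equal(weak$filter, "weak_evidence")
  expect_error(call_variants(col, error_rate = 0.6), "error_rate")
})

test_that("small call sets match a brute-force per-site enumerator", {
  s <- tiny_sim(n_samples = 12, n_sites = 50, depth = 1.0)
  flt <- deduplicate_overlaps(filter_mapq(s$reads))
  alpha <- 0.05 / genome_length(s$genome)
  calls <- call_variants(pileup(flt, s$genome), error_rate = 0.003,
                         alpha_site = alpha)
  # oracle: count alleles per (chrom, pos) directly from reads and devs,
  # apply the same binomial rule with an independent tail computation
  dv <- merge(flt$devs, flt$reads[, .(rid, chrom)], by = "rid")
  oracle <- list()
  for (key in unique(paste(dv$chrom, dv$pos))) {
    parts <- strsplit(key, " ")[[1]]
    ch <- parts[1]; po <- as.integer(parts[2])
    depth <- sum(flt$reads$chrom == ch & flt$reads$start <= po &
                   flt$reads$end >= po)
    here <- dv[dv$chrom == ch & dv$pos == po]
    for (b in unique(here$base)) {
      k <- sum(here$base == b)
      pv <- sum(dbinom(k:depth, depth, 0.001))
      if (pv <= alpha) {
        oracle[[length(oracle) + 1L]] <-
          data.table(chrom = ch, pos = po, alt = b, k = k, n = depth)
      }
    }
  }
  oracle <- rbindlist(oracle)
  setorderv(oracle, c("chrom", "pos", "alt"))
  expect_equal(nrow(calls), nrow(oracle))
  expect_equal(as.data.frame(calls[, .(chrom, pos, alt, k, n)]),
               as.data.frame(oracle))
})

test_that("strand-bias flag needs both Fisher significance and skew", {
  mk_calls <- function(rf, rr, af, ar) {
    data.table(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
               k = af + ar, n = rf + rr + af + ar,
               af = 0.1, p_value = 1e-30,
               ref_fwd = rf, ref_rev = rr, alt_fwd = af, alt_rev = ar,
               weak_evidence = FALSE)
  }
  balanced <- strand_bias_filter(mk_calls(100L, 100L, 5L, 5L))
  expect_false(balanced$strand_bias)
  skewed <- strand_bias_filter(mk_calls(100L, 100L, 20L, 0L))
  expect_true(skewed$strand_bias)
  # 100% one strand but nowhere near significant
  tiny <- strand_bias_filter(mk_calls(2L, 2L, 1L, 0L))
  expect_false(tiny$strand_bias)
  # independent hypergeometric oracle for the skewed table: two-sided
  # Fisher p = sum of probabilities of tables as or less likely
  p_oracle <- local({
    m <- 120; n_ <- 100; k <- 20
    probs <- dhyper(0:20, m, n_, k)
    sum(probs[probs <= dhyper(20, m, n_, k) * (1 + 1e-7)])
  })
  expect_lt(p_oracle, 1e-3)
  p_tiny <- local({
    probs <- dhyper(0:1, 3, 2, 1)
    sum(probs[probs <= dhyper(1, 3, 2, 1) * (1 + 1e-7)])
  })
  expect_gt(p_tiny, 1e-3)
})

test_that("sensitivity rises with pooled depth and allele frequency", {
  # columns drawn directly from the binomial read-count model
  set.seed(10)
  g <- toy_genome(3000, 0, 0, seed = 10)
  call_rate <- function(n_depth, q) {
    n_sites <- 400
    pos <- seq(2, 2 + n_sites - 1)
    ref <- substring(g$sequence$chr1, pos, pos)
    alt <- vapply(ref, function(r)
      setdiff(c("A", "C", "G", "T"), r)[1], character(1))
    k <- rbinom(n_sites, n_depth, q)
    cols <- data.table(chrom = "chr1", pos = as.integer(pos), ref = ref,
                       n = n_depth, n_fwd = n_depth, n_rev = 0L)
    for (b in c("A", "C", "G", "T")) {
      cols[[paste0(b, "_fwd")]] <- ifelse(alt == b, k, 0L)
      cols[[paste0(b, "_rev")]] <- 0L
    }
    cols$n_samples <- n_depth
    calls <- call_variants(cols, alpha_site = 1e-6, strand_p = 0)
    nrow(calls) / n_sites
  }
  for (q in c(0.05, 0.2)) {
    expect_lte(call_rate(20, q), call_rate(60, q) + 0.05)
  }
  for (d in c(20, 60)) {
    expect_lte(call_rate(d, 0.05), call_rate(d, 0.2) + 0.05)
  }
  expect_gt(call_rate(60, 0.5), 0.99)
})

test_that("the pooled AF estimator is unbiased with binomial RMSE", {
  set.seed(11)
  q <- 0.3; n <- 200; n_sites <- 5000
  k <- rbinom(n_sites, n, q)
  est <- k / n
  expect_lt(abs(mean(est) - q), 4 * sqrt(q * (1 - q) / n / n_sites))
  rmse <- sqrt(mean((est - q)^2))
  expect_lt(abs(rmse - sqrt(q * (1 - q) / n)) / sqrt(q * (1 - q) / n), 0.2)
})
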
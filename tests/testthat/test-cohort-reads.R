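test_that("fetal haplotypes are Mendelian-consistent with the mother", {
  s <- tiny_sim(n_samples = 20, n_sites = 60)
  is_x <- attr(s$cohort, "sites")$chrom == "chrX"
  for (sp in s$cohort) {
    h <- sp$hap
    # maternal gamete is one of the mother's alleles, site by site
    expect_true(all(h[, "f1"] == h[, "m1"] | h[, "f1"] == h[, "m2"]))
    # homozygous mothers force the transmitted allele
    expect_true(all(h[h[, "m1"] + h[, "m2"] == 0L, "f1"] == 0L))
    expect_true(all(h[h[, "m1"] + h[, "m2"] == 2L, "f1"] == 1L))
    expect_true(all(sp$fetal_dosage ==
                      h[, "f1"] + ifelse(is.na(h[, "f2"]), 0L, h[, "f2"])))
    if (sp$fetal_sex == "male") {
      expect_true(all(is.na(h[is_x, "f2"])))
    } else {
      expect_false(anyNA(h[, "f2"]))
    }
  }
})

test_that("p_male = 0 yields only female fetuses", {
  g <- toy_genome(5000, 500, 200, seed = 1)
  af <- simulate_population_afs(g, 20, pops = c(P = 0.01), seed = 2)
  co <- simulate_nipt_cohort(af, "P", 30, p_male = 0, seed = 3)
  expect_true(all(vapply(co, `[[`, character(1), "fetal_sex") == "female"))
  rs <- simulate_cohort_reads(co, g, af, seed = 4)
  expect_false("chrY" %in% rs$reads$chrom)
})

test_that("with zero error every deviant base is a truth alternate allele", {
  s <- tiny_sim(n_samples = 6, error_rate = 0)
  dv <- merge(s$reads$devs,
              s$reads$reads[, .(rid, chrom)], by = "rid")
  key_dev <- paste(dv$chrom, dv$pos, dv$base)
  key_alt <- paste(s$af$chrom, s$af$pos, s$af$alt)
  expect_true(all(key_dev %in% key_alt))
})

test_that("fetal fraction 0 reduces the plasma to the maternal genome", {
  g <- toy_genome(2e4, 2e3, 800, seed = 5)
  af <- simulate_population_afs(g, 50, pops = c(P = 0.01), seed = 6)
  co <- simulate_nipt_cohort(af, "P", 10,
                             fetal_fraction_dist = function(n) rep(0, n),
                             p_male = 1, seed = 7)
  rs <- simulate_cohort_reads(co, g, af, error_rate = 0,
                              seed = 8)
  # no fetal DNA: no Y reads despite male fetuses ...
  expect_false("chrY" %in% rs$reads$chrom)
  # ... and no read carries an allele absent from its mother
  dv <- merge(rs$devs, rs$reads[, .(rid, sample_id)], by = "rid")
  sites <- attr(co, "sites")
  for (i in seq_len(nrow(dv))) {
    sp <- co[[match(dv$sample_id[i],
                    vapply(co, `[[`, character(1), "sample_id"))]]
    j <- which(sites$pos == dv$pos[i])
    expect_gte(sp$maternal_dosage[j], 1L)
  }
})

test_that("a female fetus at fetal fraction 1 leaves chrY unread", {
  g <- toy_genome(1e4, 2e3, 2e3, seed = 9)
  af <- simulate_population_afs(g, 20, pops = c(P = 0.01), seed = 10)
  co <- simulate_nipt_cohort(af, "P", 5,
                             fetal_fraction_dist = function(n) rep(1, n),
                             p_male = 0, seed = 11)
  rs <- simulate_cohort_reads(co, g, af, seed = 12)
  expect_false("chrY" %in% rs$reads$chrom)
  expect_gt(nrow(rs$reads), 0)
})

test_that("reads split across chromosome copies by length x dosage weight", {
  # categorical-sampling oracle on a 3-chromosome toy genome: expected
  # read share per chromosome is the normalized mixture weight
  g <- toy_genome(c(chr1 = 6e4, chr2 = 3e4), x_bp = 0, y_bp = 2e4,
                  seed = 13)
  af <- simulate_population_afs(g, 10, pops = c(P = 0.01), seed = 14)
  co <- simulate_nipt_cohort(af, "P",
                             1, fetal_fraction_dist = function(n) rep(0.1, n),
                             p_male = 1, seed = 151)  # male fetus
  expect_equal(co[[1]]$fetal_sex, "male")
  rs <- simulate_reads(co[[1]], g, af, n_pairs = 2e5, seed = 16)
  obs <- table(rs$reads$chrom)[c("chr1", "chr2", "chrY")] / nrow(rs$reads)
  w <- c(2 * 6e4, 2 * 3e4, 0.1 * 2e4)  # per-chromosome mixture weight
  expected <- w / sum(w)
  expect_true(all(abs(obs - expected) < 4 * sqrt(expected / (2 * 2e5)) + 5e-4))
  # Y : autosome per-bp depth ratio = ff / 2 at ff = 0.1
  y_d <- sum(rs$reads$chrom == "chrY") / 2e4
  a_d <- sum(rs$reads$chrom == "chr1") / 6e4
  expect_lt(abs(y_d / a_d - 0.05), 0.01)
})

test_that("overlapping mates create depth-2 positions before filtering", {
  s <- tiny_sim(n_samples = 4, depth = 0.8)
  # insert mean 166 < 2 x 75, so mates overlap in a sizeable share of pairs
  expect_gte(max(max_depth_per_sample(s$reads, s$genome)), 2L)
})

test_that("read simulation is reproducible and seed-sensitive", {
  g <- toy_genome(1e4, 1e3, 500, seed = 1)
  af <- simulate_population_afs(g, 30, pops = c(P = 0.01), seed = 2)
  co <- simulate_nipt_cohort(af, "P", 3, seed = 3)
  a <- simulate_cohort_reads(co, g, af, seed = 4)
  b <- simulate_cohort_reads(co, g, af, seed = 4)
  c <- simulate_cohort_reads(co, g, af, seed = 5)
  expect_identical(a$reads, b$reads)
  expect_identical(a$devs, b$devs)
  expect_false(identical(a$reads, c$reads))
})

test_that("read geometry matches the insert model", {
  s <- tiny_sim(n_samples = 3)
  r <- s$reads$reads
  expect_true(all(r$end - r$start + 1L == 75L))
  expect_true(all(r$mapq >= 0 & r$mapq <= 60))
  expect_true(all(r$start >= 1))
  # mates share a fragment: per qname, the span is within the insert bounds
  span <- r[, .(span = max(end) - min(start) + 1L), by = .(sample_id, qname)]
  expect_true(all(span$span <= 500))
  expect_error(simulate_reads(s$cohort[[1]], s$genome, s$af,
                              error_rate = 0.7), "error_rate")
})
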
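test_that("panel partition honours precedence and always sums to the query", {
  q <- data.table(chrom = "chr1", pos = 1:10, ref = "A", alt = "G")
  p1 <- q[1:4]; p2 <- q[3:7]; db <- q[c(1, 8)]
  part <- partition_callset(q, list(KHV = p1, EAS = p2, db = db))
  expect_equal(part$count, c(4, 3, 1, 2))
  expect_equal(sum(part$count), nrow(q))
  expect_equal(sum(part$percent), 100)
  # internal panel order must not matter, precedence must
  part2 <- partition_callset(q, list(KHV = p1[sample(4)], EAS = p2, db = db))
  expect_equal(part2$count, part$count)
  part3 <- partition_callset(q, list(EAS = p2, KHV = p1, db = db))
  expect_equal(part3$count[part3$category == "EAS"], 5)
  # degenerate partitions
  empty <- partition_callset(q, list(A = q[0], B = q[0]))
  expect_equal(empty$count, c(0, 0, 10))
  all_in <- partition_callset(q[1:3], list(A = q))
  expect_equal(all_in$percent, c(100, 0))
  expect_error(partition_callset(rbind(q, q[1]), list(A = q)),
               "duplicate")
})

test_that("sensitivity counts common truth sites recovered by the calls", {
  g <- toy_genome(2000, 0, 0, seed = 1)
  af <- make_af_table(g, rep("chr1", 10), seq(100, 1000, by = 100),
                      list(P = rep(0.5, 10)))
  gm <- simulate_genotypes(af, "P", 30, seed = 2)
  cs <- common_sites(gm, 2)
  calls <- cs[seq_len(7)]
  expect_equal(common_snp_sensitivity(gm, calls),
               7 / nrow(cs))
  expect_equal(common_snp_sensitivity(gm, af), 1.0)
  gm0 <- gm; gm0$dosage[] <- 0L
  expect_warning(s0 <- common_snp_sensitivity(gm0, calls), "undefined")
  expect_true(is.na(s0))
  expect_equal(round(common_snp_sensitivity_counts(6889016, 7609526), 3),
               0.905)
})

test_that("AF correlation matches a two-pass covariance oracle", {
  expect_equal(af_correlation(c(.1, .2, .3), c(.1, .2, .3)), 1.0)
  expect_equal(af_correlation(c(.1, .2, .3), c(.9, .8, .7)), -1.0)
  x <- c(0.12, 0.45, 0.33, 0.8, 0.05)
  y <- c(0.10, 0.50, 0.30, 0.7, 0.09)
  oracle <- {
    mx <- sum(x) / 5; my <- sum(y) / 5
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  expect_equal(af_correlation(x, y), oracle, tolerance = 1e-12)
  expect_warning(r0 <- af_correlation(c(.2, .2), c(.1, .3)), "zero variance")
  expect_true(is.na(r0))
  # site-matched mode uses the intersection only
  est <- data.table(chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
                    af = c(.1, .2, .3, .4))
  ref <- data.table(chrom = "chr1", pos = c(2:4, 9), ref = "A", alt = "G",
                    af = c(.25, .28, .45, .9))
  expect_equal(af_correlation(est, ref),
               cor(c(.2, .3, .4), c(.25, .28, .45)))
})

test_that("sex-dosage arithmetic follows the mixture model", {
  expect_equal(male_data_fraction(0.10, 0.5), 0.05)
  expect_equal(male_data_fraction(0, 0.7), 0)
  expect_equal(male_data_fraction(0.08, 1.0), 0.08)
  expect_equal(predicted_y_depth_ratio(0.084, 0.5), 0.021)
  expect_equal(predicted_y_depth_ratio(0.1, 0), 0)
  expect_error(male_data_fraction(1.2, 0.5), "\\[0, 1\\]")
})

test_that("carrier frequency is the HWE heterozygote rate", {
  expect_equal(carrier_frequency(0), 0)
  expect_equal(carrier_frequency(0.5), 0.5)
  cf <- carrier_frequency(0.134)
  expect_equal(round(cf, 4), 0.2321)
  expect_equal(round(1 / cf), 4)       # about 1 carrier in 4-5 people
  af <- runif(20)
  expect_equal(carrier_frequency(af), carrier_frequency(1 - af))
  expect_true(all(carrier_frequency(af) <= carrier_frequency(0.5)))
})

test_that("PCA standardization reproduces a direct eigendecomposition", {
  g <- toy_genome(5e4, 0, 0, seed = 3)
  af <- simulate_population_afs(g, 300, pops = c(A = 0.1, B = 0.1),
                                seed = 4)
  ga <- simulate_genotypes(af, "A", 20, seed = 5)
  gb <- simulate_genotypes(af, "B", 20, seed = 6)
  res <- pca_genotypes(list(ga, gb), k = 3)
  expect_equal(nrow(res$scores), 40)
  expect_true(all(diff(res$varprop) <= 1e-12))
  expect_true(all(res$varprop >= 0 & res$varprop <= 1))
  # oracle: explicit covariance eigendecomposition of the standardized
  # matrix; scores agree up to sign
  G <- rbind(ga$dosage, gb$dosage)
  p <- colMeans(G) / 2
  keep <- p > 0 & p < 1
  X <- sweep(sweep(G[, keep], 2, 2 * p[keep]), 2,
             sqrt(2 * p[keep] * (1 - p[keep])), "/")
  eig <- eigen(tcrossprod(X), symmetric = TRUE)
  for (j in 1:3) {
    o <- eig$vectors[, j] * sqrt(eig$values[j])
    expect_lt(min(sum((res$scores[, j] - o)^2),
                  sum((res$scores[, j] + o)^2)), 1e-8 * sum(o^2))
  }
})

test_that("PCA separates diverged populations but not identical ones", {
  g <- toy_genome(1e5, 0, 0, seed = 7)
  af <- simulate_population_afs(g, 1500, pops = c(A = 0.1, B = 0.1),
                                seed = 8)
  ga <- simulate_genotypes(af, "A", 40, seed = 9)
  gb <- simulate_genotypes(af, "B", 40, seed = 10)
  res <- pca_genotypes(list(ga, gb))
  sil <- silhouette_score(res$scores[, 1], res$info$population)
  expect_gt(sil, 0.5)
  # F = 0 for both populations: no structure to find
  af0 <- simulate_population_afs(g, 1500, pops = c(A = 0, B = 0), seed = 11)
  res0 <- pca_genotypes(list(simulate_genotypes(af0, "A", 40, seed = 12),
                             simulate_genotypes(af0, "B", 40, seed = 13)))
  expect_lt(silhouette_score(res0$scores[, 1], res0$info$population), 0.2)
  mono <- simulate_genotypes_from_af(rep(0, 5), n_individuals = 4)
  expect_error(pca_genotypes(mono), "monomorphic")
})

test_that("pseudo-individuals from estimated AFs co-cluster with their source", {
  g <- toy_genome(1e5, 0, 0, seed = 14)
  af <- simulate_population_afs(g, 1500, pops = c(A = 0.1, B = 0.1),
                                seed = 15)
  ga <- simulate_genotypes(af, "A", 50, seed = 16)
  gb <- simulate_genotypes(af, "B", 50, seed = 17)
  est_af <- colMeans(ga$dosage) / 2   # stand-in for pooled AF estimates
  pseudo <- simulate_genotypes_from_af(est_af, sites = af[, .(chrom, pos,
                                                              ref, alt)],
                                       n_individuals = 50, label = "SIM",
                                       seed = 18)
  res <- pca_genotypes(list(pseudo, ga, gb))
  cent <- function(lab) colMeans(res$scores[res$info$population == lab, ,
                                            drop = FALSE])
  d_to_a <- sqrt(sum((cent("SIM") - cent("A"))^2))
  d_to_b <- sqrt(sum((cent("SIM") - cent("B"))^2))
  expect_lt(d_to_a, d_to_b)
})

test_that("sensitivity and AF correlation improve with cohort size", {
  g <- toy_genome(1.8e5, 1e4, 4e3, seed = 19)
  af <- simulate_population_afs(g, 800, pops = c(P = 0.01), seed = 20)
  run_n <- function(n_samples, seed) {
    co <- simulate_nipt_cohort(af, "P", n_samples,
                               depth_dist = function(n) rep(0.15, n),
                               seed = seed)
    rs <- simulate_cohort_reads(co, g, af, seed = seed + 1)
    flt <- deduplicate_overlaps(filter_mapq(rs))
    calls <- call_variants(pileup(flt, g), genome_len = genome_length(g))
    panel <- simulate_genotypes(af, "P", 99, seed = 21)
    sens <- common_snp_sensitivity(panel, calls)
    m <- merge(calls[, .(chrom, pos, ref, alt, af)],
               af[, .(chrom, pos, ref, alt, af_true = af_P)],
               by = c("chrom", "pos", "ref", "alt"))
    list(sens = sens, r = cor(m$af, m$af_true))
  }
  a <- run_n(50, 100); b <- run_n(200, 200); c <- run_n(500, 300)
  expect_lte(a$sens, b$sens + 0.05)
  expect_lte(b$sens, c$sens + 0.05)
  expect_lte(a$r, b$r + 0.02)
  expect_lte(b$r, c$r + 0.02)
  expect_gt(c$r, a$r)
})
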
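.site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = "\r")
}

#' Partition a call set against ordered reference panels
#'
#' Assigns each query site to the first panel containing it (panels are
#' ordered by precedence, first match wins) or to `novel`, and reports
#' counts and percentages with respect to the query call set — the
#' Venn-style accounting used to validate a pooled call set against
#' population panels and a variant database.
#'
#' Sites are matched exactly on (chrom, pos, ref, alt).
#'
#' @param query data.frame of called sites (`chrom`, `pos`, `ref`, `alt`);
#'   duplicate keys are an error.
#' @param panels named, ordered list of site data.frames.
#' @return a `callset_partition`: data.table with `category` (panel names
#'   in precedence order, then `"novel"`), `count`, `percent`.
#' @examples
#' q <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G")
#' partition_callset(q, list(panelA = q[1:2, ], panelB = q[1:3, ]))
#' @export
partition_callset <- function(query, panels) {
  stopifnot(is.list(panels), length(panels) >= 1L,
            !is.null(names(panels)))
  qk <- .site_key(query)
  if (anyDuplicated(qk)) stop("duplicate (chrom,pos,ref,alt) keys in query")
  assigned <- rep(NA_character_, length(qk))
  for (nm in names(panels)) {
    pk <- unique(.site_key(panels[[nm]]))
    hit <- is.na(assigned) & qk %in% pk
    assigned[hit] <- nm
  }
  assigned[is.na(assigned)] <- "novel"
  cats <- c(names(panels), "novel")
  counts <- vapply(cats, function(ct) sum(assigned == ct), numeric(1))
  out <- data.table(category = cats, count = counts,
                    percent = 100 * counts / length(qk))
  setattr(out, "class", c("callset_partition", class(out)))
  out[]
}

#' @export
print.callset_partition <- function(x, ...) {
  cat("call-set partition (first panel match wins):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %12s  (%.1f%%)\n", x$category[i],
                format(x$count[i], big.mark = ","), x$percent[i]))
  }
  invisible(x)
}

#' Sensitivity on common SNPs of a reference panel
#'
#' A truth site is "common" when at least `min_carriers` individuals of the
#' reference genotype panel carry the alternate allele.  Sensitivity is the
#' fraction of common sites present in the call set (matched on
#' chrom, pos, ref, alt).
#'
#' @param truth_genotypes a `genotype_matrix` of panel individuals.
#' @param callset data.frame of called sites.
#' @param min_carriers minimum carrier count (default 2, "shared by at
#'   least two individuals").
#' @return the sensitivity fraction in `[0, 1]`.
#' @examples
#' common_snp_sensitivity_counts(6889016, 7609526)  # 0.905
#' @export
common_snp_sensitivity <- function(truth_genotypes, callset,
                                   min_carriers = 2L) {
  cs <- common_sites(truth_genotypes, min_carriers)
  if (nrow(cs) == 0L) {
    warning("no common truth sites: sensitivity undefined")
    return(NA_real_)
  }
  mean(.site_key(cs) %in% .site_key(callset))
}

#' @rdname common_snp_sensitivity
#' @param n_recovered,n_common recovered and total common-site counts.
#' @export
common_snp_sensitivity_counts <- function(n_recovered, n_common) {
  .check_positive(n_common, "n_common")
  n_recovered / n_common
}

#' Pearson correlation between estimated and reference allele frequencies
#'
#' Computed over the matched sites only (sites present in both tables,
#' matched on chrom, pos, ref, alt), or directly over two aligned numeric
#' vectors.
#'
#' @param estimated,reference either numeric vectors of equal length, or
#'   data.frames with site keys and an `af` column.
#' @return Pearson r.
#' @export
af_correlation <- function(estimated, reference) {
  if (is.numeric(estimated) && is.numeric(reference)) {
    x <- estimated; y <- reference
  } else {
    e <- as.data.table(estimated); r <- as.data.table(reference)
    m <- match(.site_key(e), .site_key(r))
    ok <- !is.na(m)
    x <- e$af[ok]; y <- r$af[m[ok]]
  }
  if (length(x) < 2L) stop("need at least 2 matched sites")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Fraction of pooled cfDNA data of male origin
#'
#' Only the fetal share of the plasma DNA of a male-fetus pregnancy is
#' male, so the expected male fraction of the pooled data is
#' `fetal_fraction * p_male`.
#'
#' @param fetal_fraction fetal fraction in `[0, 1]`.
#' @param p_male fraction of male fetuses in `[0, 1]`.
#' @examples
#' male_data_fraction(0.10, 0.5)  # 0.05
#' @export
male_data_fraction <- function(fetal_fraction, p_male) {
  .check_prob(fetal_fraction, "fetal_fraction")
  .check_prob(p_male, "p_male")
  fetal_fraction * p_male
}

#' Chromosome-Y depth relative to genome-wide depth
#'
#' `y_depth_ratio` measures, on a read set, mean chrY depth divided by
#' mean genome-wide depth.  `predicted_y_depth_ratio` gives the mixture
#' expectation `fetal_fraction * p_male / 2`: only male fetuses contribute
#' Y DNA, with one Y copy against two autosomal copies per genome.  The
#' closed form holds when chrY is a small fraction of the genome (as in
#' the human reference, ~1.8%).
#'
#' @param read_set a `read_set`.
#' @param genome a `toy_genome` containing a Y chromosome.
#' @return the depth ratio.
#' @export
y_depth_ratio <- function(read_set, genome) {
  if (!"Y" %in% genome$chroms$class) stop("genome has no Y chromosome")
  y_chrom <- genome$chroms$chrom[genome$chroms$class == "Y"]
  r <- read_set$reads
  widths <- as.numeric(r$end - r$start + 1L)
  total <- sum(widths)
  if (total == 0) {
    warning("zero genome-wide depth: ratio undefined")
    return(NA_real_)
  }
  y_len <- sum(as.numeric(
    genome$chroms$length[genome$chroms$class == "Y"]))
  y_depth <- sum(widths[r$chrom %in% y_chrom]) / y_len
  g_depth <- total / genome_length(genome)
  y_depth / g_depth
}

#' @rdname y_depth_ratio
#' @param fetal_fraction,p_male mixture parameters in `[0, 1]`.
#' @examples
#' predicted_y_depth_ratio(0.084, 0.5)  # 0.021
#' @export
predicted_y_depth_ratio <- function(fetal_fraction, p_male) {
  .check_prob(fetal_fraction, "fetal_fraction")
  .check_prob(p_male, "p_male")
  fetal_fraction * p_male / 2
}

#' Hardy-Weinberg carrier frequency of a biallelic variant
#'
#' The heterozygote (carrier) frequency under Hardy-Weinberg equilibrium:
#' `2 * af * (1 - af)`.  Maximal (0.5) at `af = 0.5` and symmetric under
#' `af <-> 1 - af`.
#'
#' @param af allele frequency in `[0, 1]`.
#' @examples
#' carrier_frequency(0.134)  # ~0.232, about 1 carrier in 4.3
#' @export
carrier_frequency <- function(af) {
  .check_prob(af, "af")
  2 * af * (1 - af)
}

#' PCA of genotype dosage matrices (PLINK-style standardization)
#'
#' Concatenates the given genotype matrices (they must share the same site
#' set), drops monomorphic sites, centers each site column by `2 * p` and
#' scales by `sqrt(2 * p * (1 - p))` with `p` the pooled sample allele
#' frequency across all individuals, and projects individuals onto the top
#' `k` principal axes of the standardized matrix.
#'
#' @param matrices a `genotype_matrix` or list of them (e.g. real panel
#'   individuals plus pseudo-individuals simulated from estimated allele
#'   frequencies).
#' @param k number of components (default 2).
#' @return a `pca_result`: list with `scores` (individuals x k), `varprop`
#'   (explained-variance fractions, non-increasing), `info` (individual
#'   metadata with population labels).
#' @export
pca_genotypes <- function(matrices, k = 2L) {
  if (inherits(matrices, "genotype_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  ns <- vapply(matrices, function(m) ncol(m$dosage), integer(1))
  if (length(unique(ns)) != 1L)
    stop("genotype matrices must share one site set")
  G <- do.call(rbind, lapply(matrices, `[[`, "dosage"))
  info <- rbindlist(lapply(matrices, `[[`, "info"))
  if (nrow(G) < 2L) stop("need at least 2 individuals")
  p <- colMeans(G) / 2
  poly <- which(p > 0 & p < 1)
  if (!length(poly)) stop("all sites are monomorphic")
  X <- sweep(G[, poly, drop = FALSE], 2L, 2 * p[poly], "-")
  X <- sweep(X, 2L, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  sv <- svd(X, nu = min(k, nrow(X) - 1L), nv = 0L)
  k_eff <- ncol(sv$u)
  scores <- sv$u %*% diag(sv$d[seq_len(k_eff)], k_eff, k_eff)
  colnames(scores) <- paste0("PC", seq_len(k_eff))
  structure(list(
    scores = scores,
    varprop = (sv$d^2 / sum(sv$d^2))[seq_len(k_eff)],
    info = info
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d individuals, %d components (%.1f%% var on PC1)\n",
              nrow(x$scores), ncol(x$scores), 100 * x$varprop[1]))
  invisible(x)
}

#' Mean silhouette of a 1-D embedding under given labels
#'
#' Small helper to quantify cluster separation of PCA coordinates:
#' the standard silhouette index computed with Euclidean distance.
#'
#' @param coords numeric matrix (individuals x dims) or vector.
#' @param labels group labels.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Build synthetic reference panels from the simulation truth
#'
#' Emulates the panel resources a pooled call set is validated against: a
#' primary population panel (sites polymorphic among `n_primary` simulated
#' individuals of the cohort's population), a superpopulation panel (sites
#' polymorphic among individuals of a second population), and a broad
#' database panel (the union of both plus a share of the remaining truth
#' sites).  All synthetic; panel membership is the only attribute.
#'
#' @param af_table an `af_table` with at least one population.
#' @param population primary population label.
#' @param super_population optional second population label.
#' @param n_primary,n_super panel sizes (individuals).
#' @param db_extra_frac fraction of leftover truth sites added to the
#'   database panel.
#' @param seed integer seed.
#' @return named list of site data.tables, ordered by precedence, plus the
#'   attribute `panel_genotypes` holding the primary panel's
#'   `genotype_matrix` (for sensitivity computations).
#' @export
make_reference_panels <- function(af_table, population,
                                  super_population = NULL,
                                  n_primary = 99L, n_super = 200L,
                                  db_extra_frac = 0.5, seed = 1L) {
  seeds <- derive_seeds(seed, 3L, stream = 3L)
  g1 <- simulate_genotypes(af_table, population, n_primary, seed = seeds[1])
  panel1 <- common_sites(g1, min_carriers = 1L)
  panels <- setNames(list(panel1), population)
  union_keys <- .site_key(panel1)
  if (!is.null(super_population)) {
    g2 <- simulate_genotypes(af_table, super_population, n_super,
                             seed = seeds[2])
    panel2 <- common_sites(g2, min_carriers = 1L)
    panels[[super_population]] <- panel2
    union_keys <- union(union_keys, .site_key(panel2))
  }
  set.seed(seeds[3])
  all_sites <- af_table[, c("chrom", "pos", "ref", "alt")]
  left <- which(!.site_key(all_sites) %in% union_keys)
  extra <- left[runif(length(left)) < db_extra_frac]
  db <- rbind(all_sites[.site_key(all_sites) %in% union_keys],
              all_sites[extra])
  panels[["db"]] <- db
  attr(panels, "panel_genotypes") <- g1
  panels
}

#' Simulated sex-chromosome depth experiment
#'
#' Simulates a pooled NIPT cohort on a toy genome whose chrX and chrY keep
#' the human genome's length proportions (~5% and ~1.8% of the total), with
#' a fixed fetal fraction and Bernoulli fetal sex, and measures the
#' chromosome-Y to genome-wide depth ratio.  With `fetal_fraction = 0.084`
#' and `p_male = 0.5` the expected ratio is about 2.1%.
#'
#' @param n_samples cohort size (default 600).
#' @param fetal_fraction fixed fetal fraction (default 0.084).
#' @param p_male male-fetus probability (default 0.5).
#' @param depth per-sample target depth (default 0.1x, enough reads for a
#'   stable ratio at this cohort size).
#' @param seed integer seed.
#' @return list with `ratio` (Y depth / genome depth), `predicted`
#'   (closed-form expectation) and `n_samples`.
#' @export
y_depth_experiment <- function(n_samples = 600L, fetal_fraction = 0.084,
                               p_male = 0.5, depth = 0.1, seed = 1L) {
  stopifnot(n_samples >= 1)
  seeds <- derive_seeds(seed, 4L, stream = 7L)
  genome <- toy_genome(autosome_bp = 2.53e6, x_bp = 1.35e5, y_bp = 5e4,
                       seed = seeds[1])
  af <- simulate_population_afs(genome, 200, pops = c(POP1 = 0.01),
                                seed = seeds[2])
  cohort <- simulate_nipt_cohort(
    af, "POP1", n_samples,
    fetal_fraction_dist = function(n) rep(fetal_fraction, n),
    p_male = p_male, depth_dist = function(n) rep(depth, n),
    seed = seeds[3])
  reads <- simulate_cohort_reads(cohort, genome, af, error_rate = 0,
                                 seed = seeds[4])
  list(ratio = y_depth_ratio(reads, genome),
       predicted = predicted_y_depth_ratio(fetal_fraction, p_male),
       n_samples = n_samples)
}
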
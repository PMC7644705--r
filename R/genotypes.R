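#' Simulate individual genotypes under Hardy-Weinberg equilibrium
#'
#' Draws alternate-allele dosages per individual and site from the
#' population allele frequencies: Binomial(2, p) on autosomes and female X,
#' Binomial(1, p) on male X.  Y sites are never present in an
#' [simulate_population_afs()] table (the pipeline does no Y variant
#' calling), so no Y dosage arises.
#'
#' @param af_table an `af_table`.
#' @param population population label present in the table.
#' @param n_individuals number of individuals.
#' @param sex_assignment character vector recycled to `n_individuals` with
#'   values `"female"` / `"male"`, or a single probability is not accepted:
#'   pass explicit labels (default all female).
#' @param seed integer seed.
#' @return a `genotype_matrix`: list with `dosage` (individuals x sites
#'   integer matrix), `info` (data.table: `id`, `population`, `sex`) and
#'   `sites` (the af_table key columns `chrom`, `pos`, `ref`, `alt`).
#' @export
simulate_genotypes <- function(af_table, population, n_individuals,
                               sex_assignment = "female", seed = 1L) {
  stopifnot(n_individuals >= 1)
  p <- .af_column(af_table, population)
  sex <- rep_len(sex_assignment, n_individuals)
  stopifnot(all(sex %in% c("female", "male")))
  set.seed(seed)
  n_sites <- nrow(af_table)
  copies <- matrix(2L, n_individuals, n_sites)
  x_sites <- which(af_table$chrom == "chrX")
  if (length(x_sites)) copies[sex == "male", x_sites] <- 1L
  dosage <- matrix(
    rbinom(n_individuals * n_sites, size = as.vector(copies),
           prob = rep(p, each = n_individuals)),
    n_individuals, n_sites
  )
  structure(list(
    dosage = dosage,
    info = data.table(id = sprintf("%s_%04d", population,
                                   seq_len(n_individuals)),
                      population = population, sex = sex),
    sites = af_table[, c("chrom", "pos", "ref", "alt")]
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d sites (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$info$population), collapse = ", ")))
  invisible(x)
}

#' Simulate genotypes directly from an allele-frequency vector
#'
#' Treats an estimated allele-frequency vector (for instance the pooled
#' estimates of a call set) as the frequencies of a single synthetic
#' population and simulates Hardy-Weinberg genotypes from it.  This is the
#' construction used to place a pooled call set in a genotype-based PCA
#' alongside panels of real individuals.
#'
#' @param af numeric vector of allele frequencies in `[0, 1]`.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` matching `af`
#'   (optional; a placeholder is built when omitted).
#' @param n_individuals number of pseudo-individuals (default 100).
#' @param label population label for the simulated individuals.
#' @param seed integer seed.
#' @return a `genotype_matrix`.
#' @export
simulate_genotypes_from_af <- function(af, sites = NULL,
                                       n_individuals = 100L,
                                       label = "SIM", seed = 1L) {
  .check_prob(af, "af")
  if (is.null(sites)) {
    sites <- data.table(chrom = "chr1", pos = seq_along(af),
                        ref = "A", alt = "G")
  }
  stopifnot(nrow(sites) == length(af), n_individuals >= 1)
  set.seed(seed)
  dosage <- matrix(
    rbinom(n_individuals * length(af), 2L, rep(af, each = n_individuals)),
    n_individuals, length(af)
  )
  structure(list(
    dosage = dosage,
    info = data.table(id = sprintf("%s_%04d", label, seq_len(n_individuals)),
                      population = label, sex = "female"),
    sites = as.data.table(sites)
  ), class = "genotype_matrix")
}

#' Sites carried by at least `min_carriers` individuals
#'
#' A site is "common" when at least `min_carriers` individuals carry the
#' alternate allele (dosage >= 1).
#'
#' @param genotypes a `genotype_matrix`.
#' @param min_carriers minimum number of carriers (default 2).
#' @return data.table of the common sites (`chrom`, `pos`, `ref`, `alt`).
#' @export
common_sites <- function(genotypes, min_carriers = 2L) {
  carriers <- colSums(genotypes$dosage >= 1L)
  genotypes$sites[carriers >= min_carriers]
}
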
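#' @import data.table
#' @importFrom stats rbinom rbeta rnorm runif pbinom fisher.test cor setNames
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

# Substituting bases: for base i (1..4), the three possible substitution
# targets.  Row = source base index, column = 1..3.
.OTHER_BASES <- t(vapply(1:4, function(i) (1:4)[-i], integer(3)))

#' Derive a stream of child seeds from a master seed
#'
#' Every stochastic operation in the package takes an explicit integer seed.
#' Cohort-level operations derive one child seed per sample by counter so
#' that per-sample simulations are independent and reproducible regardless
#' of evaluation order.  Seeds stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param n number of child seeds.
#' @param stream integer stream offset, to separate independent uses of the
#'   same master seed.
#' @return integer vector of `n` seeds.
#' @export
derive_seeds <- function(seed, n, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0)
  # splitmix-style multiplicative hop, kept in double precision below 2^31
  base <- (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483563
  as.integer((base + 9973 * seq_len(n)) %% 2147483563 + 1)
}

.check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Truncated normal sampler by rejection (bounds are wide relative to sd in
# all defaults, so rejection terminates quickly); falls back to clamping
# after 1000 rounds to guarantee termination.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lower), upper)
  x
}

# vectorized lookup of reference bases from a genome character sequence
.ref_base_at <- function(genome, chrom, pos) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    seqstr <- genome$sequence[[ch]]
    out[i] <- substring(seqstr, pos[i], pos[i])
  }
  out
}

# Draw, for each source base, a uniform substitution to one of the other 3.
.substitute_base <- function(base) {
  idx <- match(base, BASES)
  pick <- sample.int(3L, length(base), replace = TRUE)
  BASES[.OTHER_BASES[cbind(idx, pick)]]
}
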
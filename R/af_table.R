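#' Simulate a multi-population allele-frequency table
#'
#' Draws an ancestral allele frequency per site from a (truncated) Beta site
#' frequency spectrum, then per-population alternate allele frequencies from
#' the Balding-Nichols model: for ancestral frequency p and divergence F,
#' the population frequency is Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean
#' p and variance F p (1-p).  F = 0 collapses to the ancestral frequency
#' exactly.  Sites are placed uniformly without collision on non-Y
#' chromosomes; the reference base is read from the genome and the alternate
#' base is drawn so that the truth transition/transversion ratio equals
#' `titv` in expectation (a transition with probability titv/(titv+1),
#' otherwise one of the two transversions uniformly).
#'
#' @param genome a [toy_genome()].
#' @param n_sites number of variant sites to place.
#' @param pops named numeric vector of per-population divergence parameters
#'   F (FST-like), each in `[0, 1)`; names are the population labels.
#' @param sfs_shape length-2 Beta shape for the ancestral spectrum
#'   (default `c(0.5, 0.5)`, a U-shaped spectrum with an excess of
#'   low-frequency alleles).
#' @param sfs_bounds truncation bounds for the ancestral frequency.
#' @param titv target transition/transversion ratio of the truth sites.
#' @param seed integer seed.
#' @return an `af_table`: data.table with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `anc_af`, and one `af_<pop>` column per population;
#'   attributes `pops` (the F vector) and key (chrom, pos).
#' @examples
#' g <- toy_genome(1e4, 2e3, 1e3, seed = 1)
#' af <- simulate_population_afs(g, 50, pops = c(POP1 = 0.01), seed = 2)
#' @export
simulate_population_afs <- function(genome, n_sites,
                                    pops = c(POP1 = 0.01),
                                    sfs_shape = c(0.5, 0.5),
                                    sfs_bounds = c(0.01, 0.99),
                                    titv = 2.0, seed = 1L) {
  stopifnot(n_sites >= 1, length(sfs_shape) == 2L, titv > 0)
  if (is.null(names(pops)) || any(!nzchar(names(pops))))
    stop("`pops` must be a named vector of F values")
  if (any(pops < 0 | pops >= 1))
    stop("each F must lie in [0, 1); F = 1 is degenerate")

  placeable <- genome$chroms[genome$chroms$class != "Y", ]
  if (nrow(placeable) == 0L) stop("genome has no non-Y chromosome")
  total <- sum(as.numeric(placeable$length))
  if (n_sites > total) stop("n_sites exceeds placeable positions")

  set.seed(seed)
  # collision-free placement: sample global offsets without replacement
  offs <- sort(sample(total, n_sites))
  cum <- cumsum(as.numeric(placeable$length))
  ci <- findInterval(offs - 1, cum) + 1L
  pos <- as.integer(offs - c(0, cum)[ci])
  chrom <- placeable$chrom[ci]

  ref <- .ref_base_at(genome, chrom, pos)
  alt <- .draw_alt(ref, titv)

  anc <- rbeta(n_sites, sfs_shape[1], sfs_shape[2])
  anc <- pmin(pmax(anc, sfs_bounds[1]), sfs_bounds[2])

  tab <- data.table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    anc_af = anc)
  for (p in names(pops)) {
    F <- pops[[p]]
    af <- if (F == 0) anc else {
      rbeta(n_sites, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
    }
    # rbeta returns NaN when a shape underflows to 0 (anc at the bounds);
    # those sites are fixed for the corresponding allele
    af[is.nan(af)] <- round(anc[is.nan(af)])
    tab[[paste0("af_", p)]] <- af
  }
  setkey(tab, chrom, pos)
  setattr(tab, "pops", pops)
  setattr(tab, "class", c("af_table", class(tab)))
  tab[]
}

# transition partner of each base; transversions are the other two
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

.draw_alt <- function(ref, titv) {
  n <- length(ref)
  is_ti <- runif(n) < titv / (titv + 1)
  alt <- .TRANSITION[ref]
  tv <- which(!is_ti)
  if (length(tv)) {
    # the two transversion partners: the non-ref, non-transition bases
    pick <- sample.int(2L, length(tv), replace = TRUE)
    alt[tv] <- vapply(seq_along(tv), function(j) {
      setdiff(BASES, c(ref[tv[j]], .TRANSITION[ref[tv[j]]]))[pick[j]]
    }, character(1))
  }
  unname(alt)
}

#' Population labels of an allele-frequency table
#' @param af_table an `af_table`.
#' @export
af_populations <- function(af_table) names(attr(af_table, "pops"))

.af_column <- function(af_table, population) {
  col <- paste0("af_", population)
  if (!col %in% names(af_table))
    stop(sprintf("unknown population '%s'", population))
  af_table[[col]]
}

#' Classify substitutions as transitions or transversions
#'
#' @param ref,alt character vectors of single bases.
#' @return logical vector, `TRUE` for transitions (A<->G, C<->T).
#' @export
is_transition <- function(ref, alt) unname(.TRANSITION[ref] == alt)

#' Transition/transversion ratio of a site set
#'
#' @param sites data.frame with `ref` and `alt` single-base columns.
#' @return the ratio (number of transitions / number of transversions).
#'   With zero transversions the ratio is undefined and the function
#'   returns `NA_real_` with a warning.
#' @examples
#' titv_ratio(data.frame(ref = c("A","C","A"), alt = c("G","T","C")))  # 2
#' @export
titv_ratio <- function(sites) {
  stopifnot(all(c("ref", "alt") %in% names(sites)))
  if (nrow(sites) == 0L) return(NA_real_)
  ti <- sum(is_transition(sites$ref, sites$alt))
  tv <- nrow(sites) - ti
  if (tv == 0L) {
    warning("no transversions: Ti/Tv ratio undefined")
    return(NA_real_)
  }
  ti / tv
}
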
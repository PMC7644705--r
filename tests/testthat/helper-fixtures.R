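library(data.table)

# hand-built read_set from a data.frame of read coordinates; `devs` rows
# (rid, pos, base) mark bases deviating from the reference
make_read_set <- function(reads, devs = NULL) {
  r <- as.data.table(reads)
  if (!"rid" %in% names(r)) r[, rid := .I]
  if (!"qname" %in% names(r)) r[, qname := sprintf("q%04d", .I)]
  if (!"mate" %in% names(r)) r[, mate := 1L]
  if (!"strand" %in% names(r)) r[, strand := "+"]
  if (!"mapq" %in% names(r)) r[, mapq := 60L]
  setcolorder(r, c("rid", "qname", "mate", "sample_id", "chrom",
                   "start", "end", "strand", "mapq"))
  d <- if (is.null(devs)) {
    data.table(rid = integer(), pos = integer(), base = character())
  } else as.data.table(devs)
  structure(list(reads = r, devs = d), class = "read_set")
}

# hand-built allele-frequency table over an existing genome; `afs` is a
# named list of per-population AF vectors
make_af_table <- function(genome, chrom, pos, afs, alt = NULL,
                          F_values = NULL) {
  ref <- mapply(function(ch, p) substring(genome$sequence[[ch]], p, p),
                chrom, pos, USE.NAMES = FALSE)
  if (is.null(alt)) {
    alt <- ifelse(ref == "A", "G", ifelse(ref == "G", "A",
                  ifelse(ref == "C", "T", "C")))
  }
  tab <- data.table(chrom = chrom, pos = as.integer(pos), ref = ref,
                    alt = alt, anc_af = afs[[1]])
  for (p in names(afs)) tab[[paste0("af_", p)]] <- afs[[p]]
  setkey(tab, chrom, pos)
  if (is.null(F_values)) F_values <- setNames(rep(0, length(afs)),
                                              names(afs))
  setattr(tab, "pops", F_values)
  setattr(tab, "class", c("af_table", class(tab)))
  tab[]
}

# small shared simulation used by several test files
tiny_sim <- function(n_samples = 8, n_sites = 40, depth = 0.5,
                     seed = 42, genome = NULL, error_rate = 0.003) {
  if (is.null(genome)) genome <- toy_genome(18000, 1500, 500, seed = seed)
  af <- simulate_population_afs(genome, n_sites,
                                pops = c(POP1 = 0.01, POP2 = 0.05),
                                seed = seed + 1)
  cohort <- simulate_nipt_cohort(af, "POP1", n_samples,
                                 depth_dist = function(n) rep(depth, n),
                                 seed = seed + 2)
  reads <- simulate_cohort_reads(cohort, genome, af,
                                 error_rate = error_rate, seed = seed + 3)
  list(genome = genome, af = af, cohort = cohort, reads = reads)
}

# brute-force per-position depth counter (oracle for coverage_summary)
brute_depth <- function(read_set, genome) {
  out <- list()
  for (i in seq_len(nrow(genome$chroms))) {
    ch <- genome$chroms$chrom[i]
    v <- integer(genome$chroms$length[i])
    r <- read_set$reads[read_set$reads$chrom == ch]
    for (j in seq_len(nrow(r))) {
      v[r$start[j]:r$end[j]] <- v[r$start[j]:r$end[j]] + 1L
    }
    out[[ch]] <- v
  }
  out
}

# the paper-scale fixture is expensive; build it once per test session
.paper_cache <- new.env(parent = emptyenv())
paper_scale_data <- function() {
  if (is.null(.paper_cache$fx)) {
    fx <- make_fixtures("paper_like_scaled", tempfile("paper_"), seed = 1)
    flt <- deduplicate_overlaps(filter_mapq(fx$reads))
    pile <- pileup(flt, fx$genome)
    .paper_cache$fx <- list(fx = fx, flt = flt, pile = pile)
  }
  .paper_cache$fx
}
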
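#' Default pipeline configuration
#'
#' One block per stage (`simulate`, `preprocess`, `call`, `validate`) plus
#' a global `seed` and `out_dir`.  Profiles bundle the study-scale
#' presets: `"tiny"` (3 samples, 10 kb genome — seconds), `"small"`
#' (50 samples, 100 kb), `"paper_like_scaled"` (500 samples, 1 Mb at
#' 0.15x).  All profiles keep 2 x 75 bp reads, a 0.3% error rate, fetal
#' fraction 8-10% and even fetal sex odds; chrX and chrY keep the human
#' genome's length proportions (~5% and ~1.8%).
#'
#' @param profile preset name.
#' @return nested configuration list.
#' @export
default_config <- function(profile = c("small", "tiny",
                                       "paper_like_scaled")) {
  profile <- match.arg(profile)
  sizes <- list(
    tiny = list(autosome_bp = 9300, x_bp = 500, y_bp = 200,
                n_sites = 30, n_samples = 3, depth = 0.17),
    small = list(autosome_bp = 93000, x_bp = 5000, y_bp = 2000,
                 n_sites = 300, n_samples = 50, depth = 0.17),
    paper_like_scaled = list(autosome_bp = 932000, x_bp = 50000,
                             y_bp = 18000, n_sites = 5000,
                             n_samples = 500, depth = 0.15)
  )[[profile]]
  list(
    seed = 1L,
    out_dir = "niptpool_out",
    simulate = list(
      genome = list(autosome_bp = sizes$autosome_bp, x_bp = sizes$x_bp,
                    y_bp = sizes$y_bp),
      n_sites = sizes$n_sites,
      pops = list(POP1 = 0.01, POP2 = 0.05),
      population = "POP1",
      titv = 2.0,
      sfs_shape = c(0.5, 0.5),
      n_samples = sizes$n_samples,
      fetal_fraction = list(dist = "uniform", min = 0.08, max = 0.10),
      p_male = 0.5,
      depth = sizes$depth,
      read_len = 75L,
      insert_mean = 166, insert_sd = 40, insert_max = 500,
      error_rate = 0.003
    ),
    preprocess = list(min_mapq = 30L, max_k = 5L),
    call = list(error_rate = 0.003, alpha_site = NULL, min_alt = 3L,
                strand_p = 1e-3, strand_frac = 0.9),
    validate = list(min_carriers = 2L, n_pseudo = 100L, pca_k = 2L,
                    super_population = "POP2", panel_primary_n = 99L,
                    panel_super_n = 200L, db_extra_frac = 0.5)
  )
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys (recursively, against the [default_config()]
#' schema) and checks stage parameters before any stage runs.
#'
#' @param config nested configuration list.
#' @return `config`, invisibly, on success.
#' @export
validate_config <- function(config) {
  .check_keys(config, default_config(), "config")
  s <- config$simulate
  if (is.null(s$n_samples) || s$n_samples < 1)
    stop("simulate$n_samples must be >= 1")
  if (is.null(s$n_sites) || s$n_sites < 1)
    stop("simulate$n_sites must be >= 1")
  if (!s$population %in% names(s$pops))
    stop("simulate$population must name an entry of simulate$pops")
  .check_prob(s$p_male, "simulate$p_male")
  if (s$error_rate < 0 || s$error_rate >= 0.5)
    stop("simulate$error_rate must lie in [0, 0.5)")
  invisible(config)
}

.check_keys <- function(x, schema, path) {
  extra <- setdiff(names(x), names(schema))
  if (length(extra))
    stop(sprintf("unknown configuration key%s under %s: %s",
                 if (length(extra) > 1) "s" else "", path,
                 paste(extra, collapse = ", ")))
  # pops entries are free-form population names; other nested blocks are
  # checked against the schema
  for (nm in intersect(names(x), names(schema))) {
    if (nm %in% c("pops")) next
    if (is.list(schema[[nm]]) && is.list(x[[nm]]))
      .check_keys(x[[nm]], schema[[nm]], paste(path, nm, sep = "$"))
  }
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(.merge_config(default_config(), cfg))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !nm %in% c("pops")) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[nm] <- override[nm]
    }
  }
  base
}

.ff_dist <- function(ff_cfg) {
  if (identical(ff_cfg$dist, "fixed")) {
    value <- ff_cfg$value
    function(n) rep(value, n)
  } else {
    lo <- ff_cfg$min; hi <- ff_cfg$max
    function(n) runif(n, lo, hi)
  }
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full simulate / preprocess / call / validate pipeline
#'
#' Deterministic given (config, seed): reruns produce byte-identical
#' outputs.  Each stage consumes only the previous stage's outputs; a
#' stage failure aborts with the failing stage named, retaining partial
#' outputs.  The fully-resolved configuration is written alongside the
#' outputs.
#'
#' @param config configuration list (see [default_config()]).
#' @param quiet suppress per-stage progress messages.
#' @return a `pipeline_report`: list with `coverage_raw`,
#'   `coverage_filtered`, `calls`, `partition`, `metrics` (data.table of
#'   named metrics), `pca`, and the output `paths`.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    config = file.path(config$out_dir, "config_resolved.yaml"),
    genome = file.path(config$out_dir, "genome.fa"),
    truth_vcf = file.path(config$out_dir, "truth.vcf"),
    samples = file.path(config$out_dir, "samples.tsv"),
    reads = file.path(config$out_dir, "reads.sam"),
    filtered = file.path(config$out_dir, "reads_filtered.sam"),
    coverage = file.path(config$out_dir, "coverage_per_sample.tsv"),
    calls_vcf = file.path(config$out_dir, "calls.vcf"),
    calls_tsv = file.path(config$out_dir, "calls.tsv"),
    partition = file.path(config$out_dir, "partition.tsv"),
    metrics = file.path(config$out_dir, "metrics.tsv"),
    pca = file.path(config$out_dir, "pca.tsv")
  )
  write_config(config, paths$config)
  seeds <- derive_seeds(config$seed, 6L, stream = 10L)
  log_msg <- function(...) if (!quiet) message(sprintf(...))

  # ---- simulate ----
  sim <- config$simulate
  st <- .run_stage("simulate", {
    genome <- toy_genome(sim$genome$autosome_bp, sim$genome$x_bp,
                         sim$genome$y_bp, seed = seeds[1])
    af <- simulate_population_afs(
      genome, sim$n_sites, pops = unlist(sim$pops),
      sfs_shape = sim$sfs_shape, titv = sim$titv, seed = seeds[2])
    cohort <- simulate_nipt_cohort(
      af, sim$population, sim$n_samples,
      fetal_fraction_dist = .ff_dist(sim$fetal_fraction),
      p_male = sim$p_male,
      depth_dist = function(n) rep(sim$depth, n), seed = seeds[3])
    reads <- simulate_cohort_reads(
      cohort, genome, af, read_len = sim$read_len,
      insert_mean = sim$insert_mean, insert_sd = sim$insert_sd,
      insert_max = sim$insert_max, error_rate = sim$error_rate,
      seed = seeds[4])
    write_genome_fasta(genome, paths$genome)
    write_truth(af, genome, paths$truth_vcf, cohort, paths$samples)
    write_sam(reads, genome, paths$reads)
    list(genome = genome, af = af, cohort = cohort, reads = reads)
  })
  log_msg("simulate: %d samples, %d sites, %d reads",
          length(st$cohort), nrow(st$af), nrow(st$reads$reads))

  # ---- preprocess ----
  pp <- config$preprocess
  pre <- .run_stage("preprocess", {
    cov_raw <- coverage_summary(st$reads, st$genome, max_k = pp$max_k)
    f1 <- filter_mapq(st$reads, pp$min_mapq)
    f2 <- deduplicate_overlaps(f1)
    cov_flt <- coverage_summary(f2, st$genome, max_k = pp$max_k)
    write_sam(f2, st$genome, paths$filtered)
    fwrite(cov_flt$per_sample, paths$coverage, sep = "\t")
    list(filtered = f2, cov_raw = cov_raw, cov_flt = cov_flt,
         n_in = nrow(st$reads$reads), n_mapq = nrow(f1$reads),
         n_out = nrow(f2$reads))
  })
  log_msg("preprocess: %d reads in, %d after MAPQ>=%d, %d after overlap dedup",
          pre$n_in, pre$n_mapq, pp$min_mapq, pre$n_out)

  # ---- call ----
  cl <- config$call
  calls <- .run_stage("call", {
    pile <- pileup(pre$filtered, st$genome)
    calls <- call_variants(pile, error_rate = cl$error_rate,
                           alpha_site = cl$alpha_site,
                           genome_len = genome_length(st$genome),
                           min_alt = cl$min_alt, strand_p = cl$strand_p,
                           strand_frac = cl$strand_frac)
    setorderv(calls, c("chrom", "pos", "alt"))
    calls <- calls[order(match(calls$chrom, st$genome$chroms$chrom),
                         calls$pos, calls$alt)]
    write_callset(calls, st$genome, paths$calls_vcf)
    fwrite(calls[, c("chrom", "pos", "ref", "alt", "k", "n", "af",
                     "p_value", "filter")], paths$calls_tsv, sep = "\t")
    calls
  })
  log_msg("call: %d variant calls (%d PASS)", nrow(calls),
          sum(calls$filter == "PASS"))

  # ---- validate ----
  va <- config$validate
  val <- .run_stage("validate", {
    pass <- calls[calls$filter == "PASS"]
    panels <- make_reference_panels(
      st$af, sim$population, super_population = va$super_population,
      n_primary = va$panel_primary_n, n_super = va$panel_super_n,
      db_extra_frac = va$db_extra_frac, seed = seeds[5])
    part <- partition_callset(pass, panels)
    sens <- common_snp_sensitivity(attr(panels, "panel_genotypes"), pass,
                                   min_carriers = va$min_carriers)
    truth_sites <- st$af[, c("chrom", "pos", "ref", "alt")]
    m <- match(.site_key(pass), .site_key(truth_sites))
    matched <- which(!is.na(m))
    afcor <- if (length(matched) >= 2L) {
      af_correlation(pass$af[matched],
                     .af_column(st$af, sim$population)[m[matched]])
    } else NA_real_
    ydr <- y_depth_ratio(pre$filtered, st$genome)
    tt_all <- titv_ratio(pass)
    tt_known <- titv_ratio(pass[matched])
    tt_novel <- if (length(matched) < nrow(pass)) {
      titv_ratio(if (length(matched)) pass[-matched] else pass)
    } else NA_real_

    pca <- .pipeline_pca(st$af, pass, m, sim, va, seeds[6])
    metrics <- data.table(
      metric = c("n_calls", "n_pass", "coverage_raw", "depth_raw",
                 "coverage_filtered", "depth_filtered",
                 "titv_all", "titv_known", "titv_novel",
                 "common_snp_sensitivity", "af_correlation",
                 "y_depth_ratio", "predicted_y_depth_ratio",
                 "male_data_fraction"),
      value = c(nrow(calls), nrow(pass),
                pre$cov_raw$aggregate$coverage,
                pre$cov_raw$aggregate$mean_depth,
                pre$cov_flt$aggregate$coverage,
                pre$cov_flt$aggregate$mean_depth,
                tt_all, tt_known, tt_novel, sens, afcor, ydr,
                predicted_y_depth_ratio(.mean_ff(sim), sim$p_male),
                male_data_fraction(.mean_ff(sim), sim$p_male)))
    fwrite(part, paths$partition, sep = "\t")
    fwrite(metrics, paths$metrics, sep = "\t")
    if (!is.null(pca)) {
      fwrite(data.table(pca$info, pca$scores), paths$pca, sep = "\t")
    }
    list(partition = part, metrics = metrics, pca = pca)
  })
  log_msg("validate: sensitivity %.3f, AF correlation %.3f",
          val$metrics[val$metrics$metric == "common_snp_sensitivity"]$value,
          val$metrics[val$metrics$metric == "af_correlation"]$value)

  structure(list(
    coverage_raw = pre$cov_raw, coverage_filtered = pre$cov_flt,
    calls = calls, partition = val$partition, metrics = val$metrics,
    pca = val$pca, paths = paths, config = config
  ), class = "pipeline_report")
}

.mean_ff <- function(sim) {
  ffc <- sim$fetal_fraction
  if (identical(ffc$dist, "fixed")) ffc$value else (ffc$min + ffc$max) / 2
}

# PCA joining pseudo-individuals (simulated from pooled AF estimates at
# called truth sites) with panels of simulated real individuals
.pipeline_pca <- function(af, pass, m, sim, va, seed) {
  matched <- which(!is.na(m))
  if (length(matched) < 10L) return(NULL)
  sub <- af[m[matched]]
  setattr(sub, "pops", attr(af, "pops"))
  setattr(sub, "class", c("af_table", class(sub)))
  seeds <- derive_seeds(seed, length(attr(af, "pops")) + 1L, stream = 4L)
  mats <- list(simulate_genotypes_from_af(
    pass$af[matched], sites = sub[, c("chrom", "pos", "ref", "alt")],
    n_individuals = va$n_pseudo, label = "NIPT_SIM", seed = seeds[1]))
  pops <- names(attr(af, "pops"))
  for (i in seq_along(pops)) {
    mats[[i + 1L]] <- simulate_genotypes(sub, pops[i], va$n_pseudo,
                                         seed = seeds[i + 1L])
  }
  pca_genotypes(mats, k = va$pca_k)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("niptpool pipeline report\n")
  cat(sprintf("  calls: %d (%d PASS)\n", nrow(x$calls),
              sum(x$calls$filter == "PASS")))
  print(x$partition)
  print(x$metrics)
  invisible(x)
}

#' Generate an on-disk fixture dataset
#'
#' Simulates a cohort at one of the three study scales and writes the full
#' input bundle: genome FASTA, unfiltered SAM, truth VCF, reference-panel
#' TSVs and cohort metadata.  Regenerating with the same seed reproduces
#' identical files.
#'
#' @param size `"tiny"` (3 samples, 10 kb), `"small"` (50 samples,
#'   100 kb) or `"paper_like_scaled"` (500 samples, 1 Mb at 0.15x).
#' @param dir output directory.
#' @param seed integer seed.
#' @return list with the simulated objects (`genome`, `af`, `cohort`,
#'   `reads`, `panels`) and file `paths`.
#' @export
make_fixtures <- function(size = c("tiny", "small", "paper_like_scaled"),
                          dir = tempfile("fixtures_"), seed = 1L) {
  size <- match.arg(size)
  config <- default_config(size)
  config$seed <- seed
  config$out_dir <- dir
  validate_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 6L, stream = 10L)
  sim <- config$simulate
  genome <- toy_genome(sim$genome$autosome_bp, sim$genome$x_bp,
                       sim$genome$y_bp, seed = seeds[1])
  af <- simulate_population_afs(genome, sim$n_sites,
                                pops = unlist(sim$pops),
                                sfs_shape = sim$sfs_shape,
                                titv = sim$titv, seed = seeds[2])
  cohort <- simulate_nipt_cohort(
    af, sim$population, sim$n_samples,
    fetal_fraction_dist = .ff_dist(sim$fetal_fraction),
    p_male = sim$p_male,
    depth_dist = function(n) rep(sim$depth, n), seed = seeds[3])
  reads <- simulate_cohort_reads(
    cohort, genome, af, read_len = sim$read_len,
    insert_mean = sim$insert_mean, insert_sd = sim$insert_sd,
    insert_max = sim$insert_max, error_rate = sim$error_rate,
    seed = seeds[4])
  panels <- make_reference_panels(
    af, sim$population, super_population = config$validate$super_population,
    n_primary = config$validate$panel_primary_n,
    n_super = config$validate$panel_super_n,
    db_extra_frac = config$validate$db_extra_frac, seed = seeds[5])

  paths <- list(genome = file.path(dir, "genome.fa"),
                truth_vcf = file.path(dir, "truth.vcf"),
                samples = file.path(dir, "samples.tsv"),
                reads = file.path(dir, "reads.sam"))
  write_genome_fasta(genome, paths$genome)
  write_truth(af, genome, paths$truth_vcf, cohort, paths$samples)
  write_sam(reads, genome, paths$reads)
  for (nm in names(panels)) {
    paths[[paste0("panel_", nm)]] <- file.path(dir,
                                               paste0("panel_", nm, ".tsv"))
    write_panel(panels[[nm]], paths[[paste0("panel_", nm)]])
  }
  list(genome = genome, af = af, cohort = cohort, reads = reads,
       panels = panels, config = config, paths = paths)
}
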
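.vcf_contig_lines <- function(genome) {
  sprintf("##contig=<ID=%s,length=%d>", genome$chroms$chrom,
          genome$chroms$length)
}

#' Write the simulation truth (allele-frequency table + cohort metadata)
#'
#' The truth VCF stores, per site, the ancestral allele frequency (`ANC`)
#' and one `AF_<pop>` INFO field per population, at full double precision
#' so that write/read round-trips are lossless.  Cohort metadata
#' (fetal fraction, fetal sex, target depth per sample) goes to a TSV.
#'
#' @param af_table an `af_table`.
#' @param genome the `toy_genome` (for contig headers).
#' @param vcf_path truth VCF output path.
#' @param cohort optional `nipt_cohort` whose metadata is written.
#' @param tsv_path metadata TSV path (required when `cohort` is given).
#' @return invisibly, the VCF path.
#' @export
write_truth <- function(af_table, genome, vcf_path, cohort = NULL,
                        tsv_path = NULL) {
  pops <- attr(af_table, "pops")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=niptpool_truth",
    .vcf_contig_lines(genome),
    sprintf("##population=<ID=%s,F=%.17g>", names(pops), unname(pops)),
    "##INFO=<ID=ANC,Number=1,Type=Float,Description=\"Ancestral alternate allele frequency\">",
    sprintf("##INFO=<ID=AF_%s,Number=1,Type=Float,Description=\"Alternate allele frequency in population %s\">",
            names(pops), names(pops)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(af_table)) {
    info <- sprintf("ANC=%.17g", af_table$anc_af)
    for (p in names(pops)) {
      info <- paste0(info, sprintf(";AF_%s=%.17g", p,
                                   af_table[[paste0("af_", p)]]))
    }
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                              af_table$chrom, af_table$pos, af_table$ref,
                              af_table$alt, info))
  }
  tryCatch(writeLines(lines, vcf_path),
           error = function(e) stop("truth VCF I/O failure: ",
                                    conditionMessage(e), call. = FALSE))
  if (!is.null(cohort)) {
    if (is.null(tsv_path)) stop("tsv_path required when writing a cohort")
    fwrite(cohort_metadata(cohort), tsv_path, sep = "\t")
  }
  invisible(vcf_path)
}

#' Read a truth VCF back into an `af_table`
#' @param path truth VCF path.
#' @return an `af_table` (key columns plus `anc_af` and `af_<pop>`
#'   columns; the `pops` attribute carries the per-population F).
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  pop_lines <- hdr[startsWith(hdr, "##population=")]
  pops <- numeric(0)
  if (length(pop_lines)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", pop_lines)
    Fs <- as.numeric(sub(".*F=([^,>]+).*", "\\1", pop_lines))
    pops <- setNames(Fs, ids)
  }
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    tab <- data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      anc_af = numeric())
    for (p in names(pops)) tab[[paste0("af_", p)]] <- numeric()
  } else {
    f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
    tab <- data.table(chrom = f[[1]], pos = as.integer(f[[2]]),
                      ref = f[[4]], alt = f[[5]])
    info <- f[[8]]
    grab <- function(key) {
      as.numeric(sub(sprintf(".*(?:^|;)%s=([^;]+).*", key), "\\1", info))
    }
    tab[["anc_af"]] <- grab("ANC")
    for (p in names(pops)) tab[[paste0("af_", p)]] <- grab(paste0("AF_", p))
  }
  setkey(tab, chrom, pos)
  setattr(tab, "pops", pops)
  setattr(tab, "class", c("af_table", class(tab)))
  tab[]
}

#' Write a call set as VCF
#'
#' One ALT per record (multi-allelic sites are emitted in split style).
#' INFO carries `DP` (pooled depth), `AD` (ref,alt read counts), `AF`
#' (pooled allele-frequency estimate) and `PV` (binomial tail p-value);
#' FILTER holds `PASS` or the semicolon-joined flags.
#'
#' @param calls a `variant_calls` table sorted by (chrom, pos).
#' @param genome the `toy_genome` (contig headers).
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_callset <- function(calls, genome, path) {
  if (nrow(calls)) {
    key <- match(calls$chrom, genome$chroms$chrom) * 1e10 + calls$pos
    if (anyNA(key)) stop("calls reference unknown chromosomes")
    if (is.unsorted(key)) stop("calls must be sorted by (chrom, pos)")
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=niptpool_pooled_caller",
    .vcf_contig_lines(genome),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pooled read depth\">",
    "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Pooled ref,alt read counts\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Pooled allele frequency estimate\">",
    "##INFO=<ID=PV,Number=A,Type=Float,Description=\"Binomial error-model tail p-value\">",
    "##FILTER=<ID=weak_evidence,Description=\"Fewer alternate reads than min_alt\">",
    "##FILTER=<ID=strand_bias,Description=\"Alternate support concentrated on one strand\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(calls)) {
    lines <- c(lines, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AD=%d,%d;AF=%.17g;PV=%.17g",
      calls$chrom, calls$pos, calls$ref, calls$alt, calls$filter,
      calls$n, calls$n - calls$k, calls$k, calls$af, calls$p_value))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a call-set VCF written by [write_callset()]
#' @param path VCF path.
#' @return a `variant_calls` table (`chrom`, `pos`, `ref`, `alt`, `k`,
#'   `n`, `af`, `p_value`, `filter`).
#' @export
read_callset <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    out <- data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      k = integer(), n = integer(), af = numeric(),
                      p_value = numeric(), filter = character())
    setattr(out, "class", c("variant_calls", class(out)))
    return(out)
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  info <- f[[8]]
  grab <- function(key) sub(sprintf(".*(?:^|;)%s=([^;]+).*", key), "\\1", info)
  ad <- data.table::tstrsplit(grab("AD"), ",", fixed = TRUE)
  out <- data.table(chrom = f[[1]], pos = as.integer(f[[2]]),
                    ref = f[[4]], alt = f[[5]],
                    k = as.integer(ad[[2]]),
                    n = as.integer(grab("DP")),
                    af = as.numeric(grab("AF")),
                    p_value = as.numeric(grab("PV")),
                    filter = f[[7]])
  setattr(out, "class", c("variant_calls", class(out)))
  out[]
}

#' Write / read a plain site panel (chrom, pos, ref, alt) as TSV
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param path TSV path.
#' @export
write_panel <- function(sites, path) {
  fwrite(as.data.table(sites)[, c("chrom", "pos", "ref", "alt")],
         path, sep = "\t")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  fread(path, sep = "\t", colClasses = list(
    character = c("chrom", "ref", "alt"), integer = "pos"))
}
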
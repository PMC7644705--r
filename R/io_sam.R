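#' Write a read set as a coordinate-sorted SAM file
#'
#' Emits SAM 1.6 text with `@SQ` lines from the genome, one `@RG` line per
#' sample (sample identity travels in the read group), and one alignment
#' line per read.  Sequences are reconstructed from the reference plus the
#' read set's stored deviations; CIGAR is always `<read_len>M` (the
#' simulator emits ungapped alignments) and base qualities are a constant
#' 'I'.  Mate fields (RNEXT/PNEXT/TLEN) are filled for paired reads whose
#' mate is still present.
#'
#' @param read_set a `read_set`.
#' @param genome the `toy_genome` the reads were simulated from.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(read_set, genome, path) {
  reads <- copy(read_set$reads)
  chrom_order <- genome$chroms$chrom
  reads[, "chrom_i" := match(chrom, chrom_order)]
  setorderv(reads, c("chrom_i", "start", "end", "rid"))

  seqs <- .read_sequences(reads, genome, read_set$devs)

  # mate lookup among surviving reads
  mate_key <- paste(reads$qname, 3L - reads$mate)
  mi <- match(mate_key, paste(reads$qname, reads$mate))
  has_mate <- !is.na(mi)
  flag <- 1L +                                  # paired
    ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(has_mate & reads$strand[mi] == "-", 32L, 0L) +
    ifelse(reads$mate == 1L, 64L, 128L) +
    ifelse(has_mate, 2L, 8L)                    # proper pair / mate unmapped
  rnext <- ifelse(has_mate, "=", "*")
  pnext <- ifelse(has_mate, reads$start[mi], 0L)
  tlen <- ifelse(has_mate,
                 ifelse(reads$start <= pnext,
                        pmax(reads$end[mi], reads$end) - reads$start + 1L,
                        -(reads$end - pmin(reads$start[mi], reads$start) + 1L)),
                 0L)

  rl <- reads$end - reads$start + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$chroms$chrom, genome$chroms$length),
    sprintf("@RG\tID:%s\tSM:%s", unique(reads$sample_id),
            unique(reads$sample_id))
  ), con)
  if (nrow(reads)) {
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t%s\t%s\tRG:Z:%s",
      reads$qname, flag, reads$chrom, reads$start, reads$mapq, rl,
      rnext, pnext, tlen, seqs, strrep("I", rl), reads$sample_id), con)
  }
  invisible(path)
}

# reference-plus-deviation reconstruction of read sequences
.read_sequences <- function(reads, genome, devs) {
  seqs <- character(nrow(reads))
  for (ch in unique(reads$chrom)) {
    i <- which(reads$chrom == ch)
    seqs[i] <- substring(genome$sequence[[ch]], reads$start[i], reads$end[i])
  }
  if (nrow(devs)) {
    ri <- match(devs$rid, reads$rid)
    keep <- !is.na(ri)
    off <- devs$pos[keep] - reads$start[ri[keep]] + 1L
    idx <- ri[keep]
    b <- devs$base[keep]
    for (j in seq_along(idx)) {
      substr(seqs[idx[j]], off[j], off[j]) <- b[j]
    }
  }
  seqs
}

#' Read a SAM file back into a `read_set`
#'
#' Inverse of [write_sam()]: parses alignment lines, takes the sample from
#' the `RG` tag, and recovers the sparse deviation table by comparing each
#' SEQ against the reference.  Only ungapped (`NM`-free, all-match CIGAR)
#' alignments produced by this package are supported.
#'
#' @param path SAM path.
#' @param genome the matching `toy_genome`.
#' @return a `read_set`.
#' @export
read_sam <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(.empty_read_set())
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  flag <- as.integer(f[[2]])
  rg <- rep(NA_character_, length(lines))
  for (k in seq(12, length(f))) {
    tag <- f[[k]]
    hit <- !is.na(tag) & startsWith(tag, "RG:Z:")
    rg[hit] <- substring(tag[hit], 6L)
  }
  start <- as.integer(f[[4]])
  seq <- f[[10]]
  reads <- data.table(
    rid = seq_along(lines),
    qname = f[[1]],
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    sample_id = rg,
    chrom = f[[3]],
    start = start,
    end = start + nchar(seq) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(f[[5]])
  )
  devs <- .diff_to_reference(reads, seq, genome)
  structure(list(reads = reads, devs = devs), class = "read_set")
}

.diff_to_reference <- function(reads, seq, genome) {
  out <- vector("list", 0L)
  refs <- character(nrow(reads))
  for (ch in unique(reads$chrom)) {
    i <- which(reads$chrom == ch)
    refs[i] <- substring(genome$sequence[[ch]], reads$start[i], reads$end[i])
  }
  differ <- which(refs != seq)
  for (j in differ) {
    a <- strsplit(seq[j], "")[[1]]
    b <- strsplit(refs[j], "")[[1]]
    d <- which(a != b)
    out[[length(out) + 1L]] <- data.table(
      rid = reads$rid[j], pos = reads$start[j] + d - 1L, base = a[d])
  }
  if (!length(out))
    return(data.table(rid = integer(), pos = integer(), base = character()))
  setkey(rbindlist(out), rid, pos)[]
}
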
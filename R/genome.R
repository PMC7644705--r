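#' Construct a toy reference genome
#'
#' Builds a small stand-in for a human-like reference: one or more autosomes
#' plus (optionally) one X and one Y chromosome, each with a random A/C/G/T
#' sequence.  Chromosome class drives copy-number logic downstream: mothers
#' carry two copies of autosomes and X and none of Y; fetuses carry X/Y
#' according to fetal sex.
#'
#' The default lengths keep chromosome Y at roughly 1.8% of the genome and X
#' at roughly 5%, mirroring the proportions of the human reference, because
#' sex-chromosome depth ratios depend on those proportions.
#'
#' @param autosome_bp integer vector of autosome lengths (bp), named or not.
#' @param x_bp,y_bp lengths of chrX / chrY; `0` disables the chromosome.
#' @param seed integer seed for the random sequence.
#' @return object of class `toy_genome`: list with `chroms` (data.table of
#'   `chrom`, `length`, `class`) and `sequence` (named list of character
#'   strings).
#' @examples
#' g <- toy_genome(autosome_bp = 1e4, x_bp = 2e3, y_bp = 1e3, seed = 1)
#' genome_length(g)
#' @export
toy_genome <- function(autosome_bp = 2.53e6, x_bp = 1.35e5, y_bp = 5e4,
                       seed = 1L) {
  stopifnot(length(autosome_bp) >= 1L, all(autosome_bp > 0),
            x_bp >= 0, y_bp >= 0)
  nm <- names(autosome_bp)
  if (is.null(nm)) nm <- paste0("chr", seq_along(autosome_bp))
  chroms <- data.table(
    chrom  = nm,
    length = as.integer(autosome_bp),
    class  = "autosome"
  )
  if (x_bp > 0) chroms <- rbind(chroms,
    data.table(chrom = "chrX", length = as.integer(x_bp), class = "X"))
  if (y_bp > 0) chroms <- rbind(chroms,
    data.table(chrom = "chrY", length = as.integer(y_bp), class = "Y"))
  if (anyDuplicated(chroms$chrom)) stop("chromosome names must be unique")
  set.seed(seed)
  sequence <- lapply(seq_len(nrow(chroms)), function(i) {
    paste(sample(BASES, chroms$length[i], replace = TRUE), collapse = "")
  })
  names(sequence) <- chroms$chrom
  structure(list(chroms = chroms, sequence = sequence),
            class = "toy_genome")
}

#' Total genome length in bp
#' @param genome a `toy_genome`.
#' @export
genome_length <- function(genome) sum(as.numeric(genome$chroms$length))

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %d chromosomes, %s bp total\n",
              nrow(x$chroms), format(genome_length(x), big.mark = ",")))
  print(x$chroms)
  invisible(x)
}

#' Write / read a toy genome as FASTA
#'
#' @param genome a `toy_genome`.
#' @param path output FASTA path.
#' @return `write_genome_fasta` returns `path` invisibly; `read_genome_fasta`
#'   returns a `toy_genome` (chromosome classes inferred from names `chrX` /
#'   `chrY`, all others autosomes).
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(unlist(genome$sequence))
  names(dna) <- genome$chroms$chrom
  Biostrings::writeXStringSet(dna, filepath = path, width = 70L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(dna))
  chroms <- data.table(
    chrom  = nm,
    length = Biostrings::width(dna),
    class  = ifelse(nm == "chrX", "X", ifelse(nm == "chrY", "Y", "autosome"))
  )
  sequence <- as.list(as.character(dna))
  names(sequence) <- nm
  structure(list(chroms = chroms, sequence = sequence),
            class = "toy_genome")
}
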
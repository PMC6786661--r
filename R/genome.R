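#' Genome model
#'
#' A lightweight container for the reference genome every other stage relies
#' on: ordered chromosome names and lengths, optional access to the actual
#' sequence, and the ploidy used to scale the genome size. The total base
#' count (`total_bases = ploidy * sum(chrom_lengths)`) is the denominator of
#' the per-base mutation probability in the cluster statistic and of the
#' percent-ssDNA estimate, so diploid samples are evaluated against twice the
#' reference length.
#'
#' @param chrom_names Character vector of chromosome names (ordered).
#' @param chrom_lengths Integer vector of chromosome lengths in bp, same
#'   order as `chrom_names`.
#' @param sequences Optional [Biostrings::DNAStringSet] holding the actual
#'   sequences (names must match `chrom_names`). A lengths-only model is
#'   sufficient for cluster detection; sequence access is required for motif
#'   work and simulation.
#' @param ploidy Integer >= 1; number of genome copies per cell.
#'
#' @return An object of class `genome_model` with elements `chrom_names`,
#'   `chrom_lengths` (named), `sequences` (or `NULL`), `ploidy`,
#'   `total_bases`.
#' @export
genome_model <- function(chrom_names, chrom_lengths, sequences = NULL,
                         ploidy = 1L) {
  stopifnot(length(chrom_names) == length(chrom_lengths),
            length(chrom_names) >= 1)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1 bp")
  if (anyDuplicated(chrom_names)) stop("duplicated chromosome names")
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 1L) stop("ploidy must be an integer >= 1")
  if (!is.null(sequences)) {
    if (!methods::is(sequences, "DNAStringSet"))
      sequences <- Biostrings::DNAStringSet(sequences)
    if (!setequal(names(sequences), chrom_names))
      stop("sequence names do not match chrom_names")
    sequences <- sequences[chrom_names]
    if (!all(Biostrings::width(sequences) == chrom_lengths))
      stop("sequence widths do not match chrom_lengths")
  }
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = stats::setNames(chrom_lengths, chrom_names),
         sequences = sequences,
         ploidy = ploidy,
         total_bases = ploidy * sum(chrom_lengths)),
    class = "genome_model"
  )
}

#' Load a reference genome from FASTA
#'
#' @param fasta_path Path to a (possibly gzipped) FASTA file.
#' @param ploidy Integer >= 1 passed to [genome_model()].
#' @return A `genome_model` with sequences attached.
#' @export
load_genome <- function(fasta_path, ploidy = 1L) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop("empty FASTA: ", fasta_path)
  # drop description after first whitespace, as samtools faidx would
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_model(names(seqs), Biostrings::width(seqs), sequences = seqs,
               ploidy = ploidy)
}

#' Extract genome sequence
#'
#' 1-based, fully closed coordinates on the forward (Watson) strand.
#' Returns uppercase characters; querying a lengths-only model is an error.
#'
#' @param genome A `genome_model`.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds; must lie within the chromosome.
#' @return A single character string.
#' @export
get_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(genome$sequences))
    stop("genome model has no sequences attached")
  if (!chrom %in% genome$chrom_names) stop("unknown chromosome: ", chrom)
  len <- genome$chrom_lengths[[chrom]]
  if (start < 1 || end > len || start > end)
    stop(sprintf("out-of-bounds query %s:%d-%d (length %d)",
                 chrom, start, end, len))
  toupper(as.character(Biostrings::subseq(genome$sequences[[chrom]],
                                          start, end)))
}

#' Generate a random genome
#'
#' i.i.d. bases at a given GC content, as a stand-in reference for
#' simulation and testing. Yeast-like defaults: 16 chromosomes are not
#' required; pass whatever lengths the experiment needs.
#'
#' @param chrom_lengths Named (or unnamed, then `chr1..chrN`) integer vector.
#' @param gc GC content in (0,1); C and G each get `gc/2`.
#' @param ploidy Passed to [genome_model()].
#' @return A `genome_model` with sequences.
#' @export
random_genome <- function(chrom_lengths, gc = 0.38, ploidy = 1L) {
  stopifnot(gc > 0, gc < 1)
  nms <- names(chrom_lengths)
  if (is.null(nms)) nms <- paste0("chr", seq_along(chrom_lengths))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(chrom_lengths, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  genome_model(nms, chrom_lengths,
               sequences = Biostrings::DNAStringSet(stats::setNames(seqs, nms)),
               ploidy = ploidy)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %s bp (ploidy %d => %s total bases), sequences %s\n",
              length(x$chrom_names),
              format(sum(x$chrom_lengths), big.mark = ",",
                     scientific = FALSE),
              x$ploidy,
              format(x$total_bases, big.mark = ",", scientific = FALSE),
              if (is.null(x$sequences)) "absent" else "attached"))
  invisible(x)
}
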
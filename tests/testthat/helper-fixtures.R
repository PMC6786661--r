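# Shared fixtures: small genomes and hand-built catalogs, all generated in
# code at test time.

small_genome <- function(lengths = c(chr1 = 50000, chr2 = 30000),
                         gc = 0.38, ploidy = 1L, seed = 11) {
  set.seed(seed)
  random_genome(lengths, gc = gc, ploidy = ploidy)
}

# lengths-only model: enough for the cluster statistic
yeastlike_lengths <- function(ploidy = 1L) {
  genome_model(paste0("chr", as.roman(1:16)),
               rep(12070000 / 16, 16), ploidy = ploidy)
}

make_catalog <- function(pos, ref = "C", alt = "T", chrom = "chr1",
                         sample_id = "s1") {
  n <- length(pos)
  data.frame(sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
             pos = as.integer(pos), ref = rep_len(ref, n),
             alt = rep_len(alt, n), stringsAsFactors = FALSE)
}

# a genome built from an explicit sequence string
seq_genome <- function(seqs, ploidy = 1L) {
  genome_model(names(seqs), nchar(seqs),
               sequences = Biostrings::DNAStringSet(seqs), ploidy = ploidy)
}

# independent run-length-free oracle for the cluster-type taxonomy: scans
# the pattern counting strand switches directly, no rle()
oracle_classify <- function(pattern, min_mutations = 4L) {
  if (any(pattern %in% c("A", "T"))) return("non_CG")
  if (length(pattern) < min_mutations) return("below_size_filter")
  n <- length(pattern)
  switches <- sum(pattern[-1] != pattern[-n])
  if (switches == 0)
    return(if (pattern[1] == "C") "C_coordinated" else "G_coordinated")
  if (switches == 1) {
    first_run <- match(TRUE, pattern != pattern[1]) - 1L
    second_run <- n - first_run
    if (first_run >= 2 && second_run >= 2)
      return(if (pattern[1] == "C") "CG_single_switch_5pC"
             else "CG_single_switch_5pG")
    # one side is a lone base at an end
    major <- if (first_run == 1) pattern[n] else pattern[1]
    return(if (major == "C") "C_coordinated_terminal_G"
           else "G_coordinated_terminal_C")
  }
  "CG_multiple_switch"
}

# brute-force sliding-window recount of the four enrichment tallies
oracle_enrichment_tallies <- function(mutations, genome, motif = "ytCa",
                                      window = 20L) {
  mp <- parse_motif(motif)
  rc <- revcomp(mp$motif)
  rc_pos <- nchar(mp$motif) - mp$mutated_pos + 1L
  iupac <- list(A = "A", C = "C", G = "G", T = "T", Y = c("C", "T"),
                R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
                K = c("G", "T"), M = c("A", "C"), N = c("A", "C", "G", "T"))
  match_at <- function(ch, at, pat, mpos) {
    lo <- at - mpos + 1L; hi <- lo + nchar(pat) - 1L
    if (lo < 1 || hi > length(ch)) return(FALSE)
    pc <- strsplit(pat, "")[[1]]
    all(vapply(seq_along(pc),
               function(i) ch[lo + i - 1L] %in% iupac[[pc[i]]], logical(1)))
  }
  qual <- mutations[(mutations$ref == "C" & mutations$alt == "T") |
                      (mutations$ref == "G" & mutations$alt == "A"), ]
  n_base_mut <- nrow(qual)
  n_motif_mut <- 0L; ctx_motif <- 0L; ctx_base <- 0L
  for (i in seq_len(n_base_mut)) {
    len <- genome$chrom_lengths[[qual$chrom[i]]]
    lo <- max(1L, qual$pos[i] - window)
    hi <- min(len, qual$pos[i] + window)
    ch <- strsplit(get_seq(genome, qual$chrom[i], lo, hi), "")[[1]]
    at <- qual$pos[i] - lo + 1L
    if (qual$ref[i] == "C")
      n_motif_mut <- n_motif_mut + match_at(ch, at, mp$motif, mp$mutated_pos)
    else
      n_motif_mut <- n_motif_mut + match_at(ch, at, rc, rc_pos)
    ctx_base <- ctx_base + sum(ch %in% c("C", "G"))
    # count motif occurrences (both strands) by scanning every offset
    for (start in seq_len(length(ch) - nchar(mp$motif) + 1L)) {
      pc <- strsplit(mp$motif, "")[[1]]
      if (all(vapply(seq_along(pc),
                     function(k) ch[start + k - 1L] %in% iupac[[pc[k]]],
                     logical(1))))
        ctx_motif <- ctx_motif + 1L
      rcc <- strsplit(rc, "")[[1]]
      if (all(vapply(seq_along(rcc),
                     function(k) ch[start + k - 1L] %in% iupac[[rcc[k]]],
                     logical(1))))
        ctx_motif <- ctx_motif + 1L
    }
  }
  list(n_motif_mut = n_motif_mut, n_base_mut = n_base_mut,
       ctx_motif = ctx_motif, ctx_base = ctx_base)
}

# reverse-complement a whole genome model and its catalog
revcomp_world <- function(mutations, genome) {
  seqs <- Biostrings::reverseComplement(genome$sequences)
  g2 <- genome_model(genome$chrom_names, genome$chrom_lengths,
                     sequences = seqs, ploidy = genome$ploidy)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m2 <- mutations
  m2$pos <- as.integer(genome$chrom_lengths[m2$chrom] - m2$pos + 1L)
  m2$ref <- comp[m2$ref]
  m2$alt <- comp[m2$alt]
  list(mutations = validate_mutations(m2), genome = g2)
}
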
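IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
               R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
               B = "V", D = "H", H = "D", V = "B")

#' Reverse complement of an IUPAC motif string
#' @param x Motif string (case preserved per position's role is not; output
#'   uppercase).
#' @return Reverse-complemented uppercase string.
#' @export
revcomp <- function(x) {
  ch <- rev(strsplit(toupper(x), "")[[1]])
  paste(comp_base[ch], collapse = "")
}

#' Parse a motif written with the mutated base capitalized
#'
#' The field's convention writes e.g. `ytCa`: lowercase IUPAC context with
#' the single mutated position in uppercase.
#'
#' @param motif Motif string with exactly one uppercase letter, or a fully
#'   uppercase string plus `mutated_pos`.
#' @param mutated_pos Optional explicit 1-based index of the mutated base.
#' @return list(motif = uppercase string, mutated_pos, mutated_base).
#' @export
parse_motif <- function(motif, mutated_pos = NULL) {
  ch <- strsplit(motif, "")[[1]]
  if (is.null(mutated_pos)) {
    up <- which(ch %in% LETTERS)
    if (length(up) != 1)
      stop("motif must capitalize exactly one position (or give mutated_pos)")
    mutated_pos <- up
  }
  motif <- toupper(motif)
  mb <- substr(motif, mutated_pos, mutated_pos)
  if (!mb %in% c("C", "G")) stop("mutated motif base must be C or G")
  list(motif = motif, mutated_pos = mutated_pos, mutated_base = mb)
}

# does `seq_chars[at + offset]` region match motif (uppercase chars)?
matches_motif_at <- function(seq_chars, at, motif_chars, mutated_pos) {
  lo <- at - (mutated_pos - 1L)
  hi <- lo + length(motif_chars) - 1L
  if (lo < 1 || hi > length(seq_chars)) return(FALSE)
  win <- seq_chars[lo:hi]
  all(mapply(function(b, m) b %in% IUPAC[[m]], win, motif_chars))
}

count_motif_in <- function(seqs, motif) {
  # total occurrences of IUPAC `motif` (forward orientation) in seqs
  if (length(seqs) == 0) return(0L)
  dss <- Biostrings::DNAStringSet(seqs)
  sum(Biostrings::vcountPattern(motif, dss,
                                fixed = c(pattern = FALSE, subject = TRUE)))
}

#' APOBEC motif enrichment with local context normalization
#'
#' Quantifies how strongly C->T mutations concentrate in a signature motif
#' (e.g. `tCw`, `ytCa`, `rtCa`) relative to how often the motif occurs in
#' the sequence neighbourhoods of the mutated sites:
#' \deqn{E = \frac{mut_{motif} \times ctx_{base}}{mut_{base} \times ctx_{motif}}}
#' where `mut_base` counts all C->T mutations (with G->A pooled as the
#' bottom-strand complement), `mut_motif` those whose genomic context
#' matches the motif (forward motif at C sites, reverse complement at G
#' sites), and the context tallies count motif occurrences (both strands)
#' and C+G bases within a window of `window` bp on each side of every
#' qualifying mutated site (41 nt total at the default). Significance is a
#' one-sided Fisher exact test of the mutation tally against the context
#' tally.
#'
#' @param mutations Canonical catalog (the evaluated set: e.g. all,
#'   clustered-only, or scattered-only mutations of one sample).
#' @param genome `genome_model` with sequences.
#' @param motif Motif with the mutated base capitalized (see
#'   [parse_motif()]); the mutated base must be C with `change` applying
#'   on the C-containing strand.
#' @param change Length-2 character: reference and substituted base on the
#'   motif strand (default C->T).
#' @param window Flank size in bp on each side of the mutated base
#'   (default 20, i.e. a 41-nt context).
#' @return list of class `enrichment_result`: motif, n_motif_mut,
#'   n_base_mut, ctx_motif, ctx_base, enrichment, p, undefined (logical).
#' @export
motif_enrichment <- function(mutations, genome, motif = "ytCa",
                             change = c("C", "T"), window = 20L) {
  stopifnot(inherits(genome, "genome_model"))
  mutations <- validate_mutations(mutations, genome = genome)
  mf <- parse_motif(motif)
  if (mf$mutated_base != "C")
    stop("write the motif on its C-containing strand")
  rc_motif <- revcomp(mf$motif)
  rc_mutated_pos <- nchar(mf$motif) - mf$mutated_pos + 1L
  fwd <- mutations$ref == change[1] & mutations$alt == change[2]
  rev_ <- mutations$ref == comp_base[[change[1]]] &
    mutations$alt == comp_base[[change[2]]]
  qual <- mutations[fwd | rev_, , drop = FALSE]
  is_fwd <- qual$ref == change[1]
  n_base_mut <- nrow(qual)
  n_motif_mut <- 0L
  windows <- character(n_base_mut)
  motif_chars_f <- strsplit(mf$motif, "")[[1]]
  motif_chars_r <- strsplit(rc_motif, "")[[1]]
  for (i in seq_len(n_base_mut)) {
    chrom <- qual$chrom[i]; pos <- qual$pos[i]
    len <- genome$chrom_lengths[[chrom]]
    lo <- max(1L, pos - window); hi <- min(len, pos + window)
    win <- get_seq(genome, chrom, lo, hi)
    windows[i] <- win
    ch <- strsplit(win, "")[[1]]
    at <- pos - lo + 1L
    hit <- if (is_fwd[i])
      matches_motif_at(ch, at, motif_chars_f, mf$mutated_pos)
    else
      matches_motif_at(ch, at, motif_chars_r, rc_mutated_pos)
    n_motif_mut <- n_motif_mut + hit
  }
  ctx_motif <- count_motif_in(windows, mf$motif) +
    count_motif_in(windows, rc_motif)
  ctx_base <- if (n_base_mut)
    sum(Biostrings::letterFrequency(Biostrings::DNAStringSet(windows),
                                    c("C", "G")))
  else 0L
  undefined <- n_base_mut == 0 || ctx_motif == 0
  enr <- if (undefined) NA_real_ else
    (n_motif_mut * ctx_base) / (n_base_mut * ctx_motif)
  p <- if (undefined) NA_real_ else
    stats::fisher.test(matrix(c(n_motif_mut, n_base_mut - n_motif_mut,
                                ctx_motif, ctx_base - ctx_motif), 2,
                              byrow = TRUE),
                       alternative = "greater")$p.value
  structure(list(motif = motif, n_motif_mut = as.integer(n_motif_mut),
                 n_base_mut = as.integer(n_base_mut),
                 ctx_motif = as.integer(ctx_motif),
                 ctx_base = as.integer(ctx_base),
                 enrichment = enr, p = p, undefined = undefined),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("motif %s: %d/%d mutations in motif, %d/%d context sites; enrichment %.3f (p = %.3g)\n",
              x$motif, x$n_motif_mut, x$n_base_mut, x$ctx_motif,
              x$ctx_base, x$enrichment, x$p))
  invisible(x)
}

#' Enrichment stratified by cluster membership
#'
#' Computes [motif_enrichment()] for three mutation sets of each sample:
#' all mutations, clustered mutations only, and scattered (unclustered)
#' mutations only, mirroring per-sample summary tables with
#' `sum_all` / `sum_cluster` / `sum_scattered` columns.
#'
#' @param calls `cluster_calls` object (cluster membership provides the
#'   strata).
#' @param genome `genome_model` with sequences.
#' @param motif,change,window Passed to [motif_enrichment()].
#' @return data.frame with one row per sample x stratum: sample_id,
#'   stratum, all tallies, enrichment, p.
#' @export
stratified_enrichment <- function(calls, genome, motif = "ytCa",
                                  change = c("C", "T"), window = 20L) {
  stopifnot(inherits(calls, "cluster_calls"))
  mut <- calls$mutations
  rows <- list()
  for (s in unique(mut$sample_id)) {
    ms <- mut[mut$sample_id == s, ]
    sets <- list(all = ms,
                 clustered = ms[!is.na(ms$cluster_id), ],
                 scattered = ms[is.na(ms$cluster_id), ])
    for (nm in names(sets)) {
      st <- sets[[nm]]
      if (nrow(st) == 0) {
        rows[[paste(s, nm)]] <- data.frame(
          sample_id = s, stratum = nm, motif = motif,
          n_motif_mut = 0L, n_base_mut = 0L, ctx_motif = 0L, ctx_base = 0L,
          enrichment = NA_real_, p = NA_real_)
        next
      }
      e <- motif_enrichment(st[, c("sample_id", "chrom", "pos", "ref",
                                   "alt")],
                            genome, motif = motif, change = change,
                            window = window)
      rows[[paste(s, nm)]] <- data.frame(
        sample_id = s, stratum = nm, motif = motif,
        n_motif_mut = e$n_motif_mut, n_base_mut = e$n_base_mut,
        ctx_motif = e$ctx_motif, ctx_base = e$ctx_base,
        enrichment = e$enrichment, p = e$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
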
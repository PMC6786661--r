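#' Simulation configuration
#'
#' Generative model for catalogs with the mechanistic structure of
#' DSB-repair hypermutation. Each simulated break exposes single-stranded
#' DNA whose cytosines deaminate (C->U, fixed as C->T on the exposed
#' strand), with a strong preference for a signature motif:
#'
#' * `bidirectional_resection`: both sides of a two-ended break are
#'   resected 5'->3'; the left tract exposes the top strand (top-strand
#'   C->T) and the right tract the bottom strand (read as G->A on top),
#'   so a surviving cluster reads 5'C...3'G.
#' * `unidirectional_resection`: one end only; a fair coin picks the side,
#'   yielding an all-C or all-G coordinated tract.
#' * `bir`: break-induced replication leaves a long single-stranded tail
#'   behind the migrating bubble on one side; geometrically like the
#'   unidirectional case, with (by default) longer tracts.
#'
#' Defaults emulate the study conditions: tract lengths lognormal with
#' median 5 kb (order of observed cluster-length medians), per-motif-site
#' deamination probability 0.055 with a 20:1 preference for motif sites
#' over other cytosines — together about 1 mutation/kb of tract on a
#' GC-0.38 genome — and a scattered background of 2.5e-6 SNVs/bp (about
#' 30 per haploid yeast genome).
#'
#' @param n_dsb Number of double-strand breaks to place.
#' @param mechanism_mix Named probabilities over
#'   `c(bidirectional_resection, unidirectional_resection, bir)`; must sum
#'   to 1.
#' @param tract_meanlog,tract_sdlog Lognormal parameters of per-side tract
#'   length in bp.
#' @param bir_meanlog BIR tail lengths use this meanlog (default: 2x the
#'   median of resection tracts).
#' @param deamination_rate Probability a motif-matching exposed C
#'   deaminates.
#' @param residual_ratio Motif-site rate over non-motif C rate.
#' @param motif Preferred signature motif, mutated base capitalized.
#' @param background_rate Scattered SNVs per bp (uniform positions and
#'   substitution spectrum).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_dsb = 10L,
                       mechanism_mix = c(bidirectional_resection = 1/3,
                                         unidirectional_resection = 1/3,
                                         bir = 1/3),
                       tract_meanlog = log(5000), tract_sdlog = 0.5,
                       bir_meanlog = log(10000),
                       deamination_rate = 0.055, residual_ratio = 20,
                       motif = "ytCa", background_rate = 2.5e-6) {
  mechs <- c("bidirectional_resection", "unidirectional_resection", "bir")
  if (!all(names(mechanism_mix) %in% mechs))
    stop("mechanism_mix names must be among: ", paste(mechs, collapse = ", "))
  mix <- stats::setNames(numeric(3), mechs)
  mix[names(mechanism_mix)] <- mechanism_mix
  if (abs(sum(mix) - 1) > 1e-8) stop("mechanism_mix must sum to 1")
  stopifnot(n_dsb >= 0, deamination_rate >= 0, deamination_rate <= 1,
            residual_ratio >= 1, background_rate >= 0,
            background_rate <= 1)
  structure(list(n_dsb = as.integer(n_dsb), mechanism_mix = mix,
                 tract_meanlog = tract_meanlog, tract_sdlog = tract_sdlog,
                 bir_meanlog = bir_meanlog,
                 deamination_rate = deamination_rate,
                 residual_ratio = residual_ratio,
                 motif = motif, background_rate = background_rate),
            class = "sim_config")
}

# Deaminate exposed cytosines of one ssDNA segment.
# strand "top": top-strand C->T; "bottom": bottom-strand C, read as G->A.
deaminate_segment <- function(genome, chrom, start, end, strand, config,
                              motif_parsed) {
  if (end < start) return(NULL)
  len <- genome$chrom_lengths[[chrom]]
  flank <- nchar(motif_parsed$motif)
  lo <- max(1L, start - flank); hi <- min(len, end + flank)
  seq <- get_seq(genome, chrom, lo, hi)
  ch <- strsplit(seq, "")[[1]]
  target <- if (strand == "top") "C" else "G"
  sites_local <- which(ch == target)
  sites <- sites_local + lo - 1L
  keep <- sites >= start & sites <= end
  sites_local <- sites_local[keep]; sites <- sites[keep]
  if (length(sites) == 0) return(NULL)
  pat <- if (strand == "top") motif_parsed$motif else
    revcomp(motif_parsed$motif)
  mpos <- if (strand == "top") motif_parsed$mutated_pos else
    nchar(motif_parsed$motif) - motif_parsed$mutated_pos + 1L
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq),
                                fixed = c(pattern = FALSE, subject = TRUE))
  motif_local <- Biostrings::start(m) + mpos - 1L
  in_motif <- sites_local %in% motif_local
  rate <- ifelse(in_motif, config$deamination_rate,
                 config$deamination_rate / config$residual_ratio)
  hit <- stats::runif(length(sites)) < rate
  if (!any(hit)) return(NULL)
  data.frame(chrom = chrom, pos = sites[hit],
             ref = target, alt = if (strand == "top") "T" else "A",
             stringsAsFactors = FALSE)
}

place_positions <- function(genome, n) {
  # uniform over the (haploid) genome; returns chrom + pos
  lens <- genome$chrom_lengths
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
  pos <- vapply(chrom, function(cc) sample.int(lens[[cc]], 1), integer(1))
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate a DSB-repair hypermutation catalog
#'
#' Places `n_dsb` breaks uniformly on the genome, draws a repair mechanism
#' per break, exposes the corresponding ssDNA segments, deaminates exposed
#' cytosines per [sim_config()], and adds a uniform scattered background.
#' With `copies > 1` (e.g. a diploid as two unphased haploid copies),
#' breaks and background are spread over the copies and the per-copy
#' catalogs merged without phase.
#'
#' @param genome `genome_model` with sequences (its `ploidy` is not used
#'   here; pass `copies`).
#' @param config `sim_config`.
#' @param sample_id Sample name for the emitted catalog.
#' @param copies Number of independent genome copies (default 1).
#' @param seed Optional integer seed for reproducibility.
#' @return list: `mutations` (canonical catalog), `truth` with `events`
#'   (event_id, copy, mechanism, chrom, break_pos) and `segments`
#'   (event_id, chrom, start, end, strand, truncated), and `config`.
#' @export
simulate_catalog <- function(genome, config = sim_config(),
                             sample_id = "sim", copies = 1L, seed = NULL) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  if (is.null(genome$sequences))
    stop("simulation needs genome sequences")
  if (!is.null(seed)) set.seed(seed)
  mp <- parse_motif(config$motif)
  events <- list(); segments <- list(); muts <- list()
  n_dsb <- config$n_dsb
  if (n_dsb > 0) {
    brk <- place_positions(genome, n_dsb)
    mech <- sample(names(config$mechanism_mix), n_dsb, replace = TRUE,
                   prob = config$mechanism_mix)
    copy <- sample.int(copies, n_dsb, replace = TRUE)
    for (i in seq_len(n_dsb)) {
      cc <- brk$chrom[i]; b <- brk$pos[i]
      len <- genome$chrom_lengths[[cc]]
      eid <- sprintf("ev%03d", i)
      meanlog <- if (mech[i] == "bir") config$bir_meanlog else
        config$tract_meanlog
      draw_len <- function() max(1L, round(stats::rlnorm(1, meanlog,
                                                         config$tract_sdlog)))
      segs <- list()
      if (mech[i] == "bidirectional_resection") {
        lL <- draw_len(); lR <- draw_len()
        segs[[1]] <- c(start = b - lL, end = b - 1, strand = "top")
        segs[[2]] <- c(start = b, end = b + lR - 1, strand = "bottom")
      } else {
        l1 <- draw_len()
        if (stats::runif(1) < 0.5)
          segs[[1]] <- c(start = b - l1, end = b - 1, strand = "top")
        else
          segs[[1]] <- c(start = b, end = b + l1 - 1, strand = "bottom")
      }
      events[[eid]] <- data.frame(event_id = eid, copy = copy[i],
                                  mechanism = mech[i], chrom = cc,
                                  break_pos = b, stringsAsFactors = FALSE)
      for (sg in segs) {
        s0 <- as.integer(sg[["start"]]); e0 <- as.integer(sg[["end"]])
        s1 <- max(1L, s0); e1 <- min(len, e0)
        if (e1 < s1) next
        segments[[length(segments) + 1L]] <-
          data.frame(event_id = eid, chrom = cc, start = s1, end = e1,
                     strand = sg[["strand"]],
                     truncated = (s1 != s0) || (e1 != e0),
                     stringsAsFactors = FALSE)
        dm <- deaminate_segment(genome, cc, s1, e1, sg[["strand"]],
                                config, mp)
        if (!is.null(dm)) {
          dm$event_id <- eid
          muts[[length(muts) + 1L]] <- dm
        }
      }
    }
  }
  # scattered background over all copies
  n_bg <- stats::rpois(1, config$background_rate * copies *
                         sum(genome$chrom_lengths))
  if (n_bg > 0) {
    bg <- place_positions(genome, n_bg)
    bg$ref <- vapply(seq_len(n_bg), function(i)
      get_seq(genome, bg$chrom[i], bg$pos[i], bg$pos[i]), character(1))
    bg <- bg[bg$ref %in% BASES, , drop = FALSE]
    bg$alt <- vapply(bg$ref, function(r)
      sample(setdiff(BASES, r), 1), character(1))
    bg$event_id <- NA_character_
    if (nrow(bg)) muts[[length(muts) + 1L]] <- bg
  }
  mut <- if (length(muts)) do.call(rbind, muts) else
    cbind(empty_catalog()[-1], event_id = character())
  truth_events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(), copy = integer(),
               mechanism = character(), chrom = character(),
               break_pos = integer(), stringsAsFactors = FALSE)
  truth_segments <- if (length(segments)) do.call(rbind, segments) else
    data.frame(event_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               truncated = logical(), stringsAsFactors = FALSE)
  rownames(truth_events) <- rownames(truth_segments) <- NULL
  if (nrow(mut)) {
    mut$sample_id <- sample_id
    # unphased merge across copies/events: identical sites collapse
    key <- paste(mut$chrom, mut$pos)
    mut <- mut[!duplicated(key), ]
    event_of <- stats::setNames(mut$event_id, paste(mut$chrom, mut$pos))
    cat_df <- validate_mutations(
      mut[, c("sample_id", "chrom", "pos", "ref", "alt")])
    cat_df$event_id <- unname(event_of[paste(cat_df$chrom, cat_df$pos)])
  } else {
    cat_df <- empty_catalog()
    cat_df$event_id <- character(0)
  }
  list(mutations = cat_df,
       truth = list(events = truth_events, segments = truth_segments),
       config = config)
}

#' Simulate a null (uniformly scattered) catalog
#'
#' Positions are uniform over the genome without replacement; alternate
#' alleles are uniform over the three non-reference bases. Works on a
#' lengths-only genome model (random reference alleles are then drawn),
#' which suffices for exercising the cluster statistic.
#'
#' @param genome `genome_model`.
#' @param n_mutations Number of SNVs.
#' @param sample_id Sample name.
#' @param seed Optional integer seed.
#' @return Canonical catalog data.frame.
#' @export
simulate_null <- function(genome, n_mutations, sample_id = "null",
                          seed = NULL) {
  stopifnot(inherits(genome, "genome_model"),
            n_mutations <= sum(genome$chrom_lengths))
  if (!is.null(seed)) set.seed(seed)
  if (n_mutations == 0) return(empty_catalog())
  lens <- genome$chrom_lengths
  offsets <- cumsum(c(0, lens[-length(lens)]))
  names(offsets) <- names(lens)
  flat <- sample(sum(lens), n_mutations)
  idx <- findInterval(flat - 1, cumsum(lens), left.open = FALSE) + 1L
  chrom <- names(lens)[idx]
  pos <- as.integer(flat - offsets[chrom])
  ref <- if (!is.null(genome$sequences))
    vapply(seq_len(n_mutations), function(i)
      get_seq(genome, chrom[i], pos[i], pos[i]), character(1))
  else sample(BASES, n_mutations, replace = TRUE)
  keep <- ref %in% BASES
  alt <- vapply(ref[keep], function(r) sample(setdiff(BASES, r), 1),
                character(1))
  validate_mutations(data.frame(sample_id = sample_id, chrom = chrom[keep],
                                pos = pos[keep], ref = ref[keep], alt = alt,
                                stringsAsFactors = FALSE))
}

#' Write simulation truth segments as BED
#'
#' One row per ssDNA segment; name field carries
#' `event_id|mechanism|strand`.
#'
#' @param truth `$truth` element of [simulate_catalog()] output.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  seg <- merge(truth$segments,
               truth$events[, c("event_id", "mechanism")], by = "event_id")
  bed <- data.frame(seg$chrom, seg$start - 1L, seg$end,
                    paste(seg$event_id, seg$mechanism, seg$strand,
                          sep = "|"))
  bed <- bed[order(bed[[1]], bed[[2]]), ]
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
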
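#' Collapse complex events
#'
#' Mutations of one sample and chromosome that lie < `max_gap` bp apart are
#' chained into a single "complex" event and counted once in the cluster
#' statistic, because they may derive from a single mutagenic lesion rather
#' than independent hits. Chaining is maximal: a run of consecutive
#' distances all < `max_gap` becomes one event.
#'
#' @param pos Sorted integer vector of mutation positions (one sample, one
#'   chromosome).
#' @param max_gap Distances strictly below this collapse (default 10 bp).
#' @return data.frame with one row per collapsed event: `start`, `end`,
#'   `n_members`, and `first_idx`/`last_idx` indexing into `pos`.
#' @export
collapse_complexes <- function(pos, max_gap = 10L) {
  stopifnot(max_gap >= 1)
  if (length(pos) == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_members = integer(), first_idx = integer(),
                      last_idx = integer()))
  if (is.unsorted(pos, strictly = TRUE))
    stop("positions must be strictly increasing")
  brk <- c(TRUE, diff(pos) >= max_gap)     # TRUE starts a new event
  id <- cumsum(brk)
  first <- which(brk)
  last <- c(first[-1] - 1L, length(pos))
  data.frame(start = pos[first], end = pos[last],
             n_members = last - first + 1L,
             first_idx = first, last_idx = last)
}

#' Group collapsed events into cluster candidates
#'
#' Maximal chains of events whose consecutive nearest-edge distances
#' (start of the right event minus end of the left) are at most
#' `max_distance` form one candidate group. Singleton groups are retained
#' but are not testable by the cluster statistic.
#'
#' @param events data.frame from [collapse_complexes()].
#' @param max_distance Largest inter-event distance kept in one group
#'   (default 10 kb).
#' @return `events` with an added integer column `group`.
#' @export
group_candidates <- function(events, max_distance = 10000L) {
  stopifnot(max_distance > 0)
  n <- nrow(events)
  if (n == 0) {
    events$group <- integer(0)
    return(events)
  }
  gap <- events$start[-1] - events$end[-n]
  events$group <- cumsum(c(TRUE, gap > max_distance))
  events
}

#' Negative-binomial cluster P-value
#'
#' Probability of observing `k - 1` mutations within `x - 1` or fewer bases
#' under a uniform per-base mutation probability `pi`:
#' \deqn{p = \sum_{j=0}^{x-k} \binom{k+j-2}{j} (1-\pi)^j \pi^{k-1}}
#' i.e. the lower tail of a negative binomial with `k - 1` successes of
#' probability `pi`, evaluated at `x - k` failures. Accumulated in log
#' space so that large `k` and tiny `pi` stay numerically stable.
#'
#' @param k Number of (collapsed) mutation events in the group, >= 2.
#' @param x Group span in bp (last event end - first event start + 1),
#'   >= `k`.
#' @param pi Per-base mutation probability in (0, 1): total collapsed
#'   mutations of the sample over total genome bases.
#' @return P-value in (0, 1].
#' @export
cluster_pvalue <- function(k, x, pi) {
  k <- as.numeric(k); x <- as.numeric(x)
  if (length(k) != 1 || length(x) != 1 || length(pi) != 1)
    stop("cluster_pvalue() is scalar; vectorize with vapply()")
  if (is.na(k) || k < 2) stop("k must be >= 2")
  if (is.na(x) || x < k) stop("x must be >= k")
  if (is.na(pi) || pi <= 0 || pi >= 1) stop("pi must lie in (0, 1)")
  jmax <- x - k
  # sum the negative-binomial pmf over j = 0..jmax by multiplicative
  # recurrence, scaled at the largest in-range term so only one exp/log
  # round trip touches the result: t_{j+1}/t_j = (k+j-1)/(j+1) * (1-pi)
  j0 <- min(max(0, floor((k - 1) * (1 - pi) / pi)), jmax)
  lt0 <- lchoose(k + j0 - 2, j0) + j0 * log1p(-pi) + (k - 1) * log(pi)
  s <- 1
  t <- 1; j <- j0
  while (j < jmax) {
    t <- t * (k + j - 1) / (j + 1) * (1 - pi)
    j <- j + 1
    s <- s + t
    if (t < s * 1e-17 && j > (k - 1) * (1 - pi) / pi) break
  }
  t <- 1; j <- j0
  while (j > 0) {
    t <- t * j / ((k + j - 2) * (1 - pi))
    j <- j - 1
    s <- s + t
    if (t < s * 1e-17) break
  }
  p <- exp(lt0 + log(s))
  min(p, 1)
}

#' Parse a "chrom:start-end" interval
#' @param x Interval string or a list with `chrom`, `start`, `end`.
#' @return list(chrom, start, end)
#' @export
parse_interval <- function(x) {
  if (is.list(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    return(x[c("chrom", "start", "end")])
  }
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse interval: ", x)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Detect mutation clusters
#'
#' Full cluster-calling procedure per sample: complex events (< `max_gap`
#' bp) are collapsed and counted once; collapsed events are chained into
#' candidate groups at inter-event distances up to `max_distance`; each
#' group of k >= 2 events is scored with [cluster_pvalue()] against the
#' sample's genome-wide rate `pi` (collapsed events / total genome bases);
#' groups with p <= `p_threshold` are bona fide clusters. Reported cluster
#' length is the distance between the bordering mutations (no +1), while
#' the statistic's span `x` is end - start + 1.
#'
#' @param mutations Canonical catalog (any number of samples); validated.
#' @param genome `genome_model` supplying total bases at the right ploidy.
#' @param p_threshold Significance cutoff (default 1e-4).
#' @param max_gap Complex-event collapsing distance (default 10 bp).
#' @param max_distance Candidate chaining distance (default 10 kb).
#' @param reporter Optional interval ("chrII:100-200" or list) marking the
#'   selected-reporter region; clusters overlapping it are `selected`.
#' @return Object of class `cluster_calls`: list with `clusters` (one row
#'   per cluster: sample_id, cluster_id, chrom, start, end, length,
#'   n_mutations, k, x, p_value, selected), `mutations` (input plus a
#'   `cluster_id` column, NA for scattered), and `pi` per sample.
#' @export
detect_clusters <- function(mutations, genome, p_threshold = 1e-4,
                            max_gap = 10L, max_distance = 10000L,
                            reporter = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  mutations <- validate_mutations(mutations, genome = genome)
  pos_key <- paste(mutations$sample_id, mutations$chrom, mutations$pos)
  if (anyDuplicated(pos_key))
    stop("two mutations at one position in one sample (e.g. ",
         pos_key[duplicated(pos_key)][1],
         "); deduplicate or drop multi-allelic splits before detection")
  if (!is.null(reporter)) reporter <- parse_interval(reporter)
  mutations$cluster_id <- rep(NA_character_, nrow(mutations))
  clusters <- list()
  pis <- c()
  for (s in unique(mutations$sample_id)) {
    si <- which(mutations$sample_id == s)
    # pi: collapsed events genome-wide over total bases
    n_events <- 0L
    per_chrom <- list()
    for (cc in unique(mutations$chrom[si])) {
      ci <- si[mutations$chrom[si] == cc]
      ev <- collapse_complexes(mutations$pos[ci], max_gap = max_gap)
      per_chrom[[cc]] <- list(idx = ci, events = ev)
      n_events <- n_events + nrow(ev)
    }
    pi_s <- n_events / genome$total_bases
    pis[s] <- pi_s
    if (n_events == 0) {
      message("sample ", s, ": no mutations, skipped")
      next
    }
    if (pi_s >= 1) stop("sample ", s, ": mutation rate >= 1 per base")
    cid <- 0L
    for (cc in names(per_chrom)) {
      ci <- per_chrom[[cc]]$idx
      ev <- group_candidates(per_chrom[[cc]]$events,
                             max_distance = max_distance)
      for (g in unique(ev$group)) {
        rows <- ev[ev$group == g, , drop = FALSE]
        k <- nrow(rows)
        if (k < 2) next
        x <- rows$end[k] - rows$start[1] + 1
        p <- cluster_pvalue(k, x, pi_s)
        if (p <= p_threshold) {
          cid <- cid + 1L
          first_pos <- rows$start[1]
          last_pos <- rows$end[k]
          n_raw <- sum(rows$n_members)
          id <- sprintf("%s_c%03d", s, cid)
          mi <- ci[rows$first_idx[1]:rows$last_idx[k]]
          mutations$cluster_id[mi] <- id
          sel <- !is.null(reporter) && cc == reporter$chrom &&
            first_pos <= reporter$end && last_pos >= reporter$start
          clusters[[id]] <- data.frame(
            sample_id = s, cluster_id = id, chrom = cc,
            start = first_pos, end = last_pos,
            length = last_pos - first_pos,
            n_mutations = n_raw, k = k, x = x, p_value = p,
            selected = sel, stringsAsFactors = FALSE)
        }
      }
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(sample_id = character(), cluster_id = character(),
               chrom = character(), start = integer(), end = integer(),
               length = integer(), n_mutations = integer(), k = integer(),
               x = integer(), p_value = numeric(), selected = logical(),
               stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, mutations = mutations, pi = pis,
                 params = list(p_threshold = p_threshold, max_gap = max_gap,
                               max_distance = max_distance,
                               reporter = reporter)),
            class = "cluster_calls")
}

#' @export
print.cluster_calls <- function(x, ...) {
  cat(sprintf("cluster_calls: %d cluster(s) in %d sample(s); %d of %d mutations clustered\n",
              nrow(x$clusters), length(x$pi),
              sum(!is.na(x$mutations$cluster_id)), nrow(x$mutations)))
  invisible(x)
}

#' Mutations of one cluster, in positional order
#' @param calls `cluster_calls` object.
#' @param cluster_id Cluster identifier.
#' @return data.frame of the member mutations.
#' @export
cluster_members <- function(calls, cluster_id) {
  m <- calls$mutations[!is.na(calls$mutations$cluster_id) &
                         calls$mutations$cluster_id == cluster_id, ]
  m[order(m$pos), ]
}

#' Write cluster calls as BED and detail TSV
#'
#' BED uses 0-based half-open starts, name `sample:cluster_id`, score
#' `-log10(p)` capped at 1000.
#'
#' @param calls `cluster_calls` object.
#' @param bed_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the cluster table.
#' @export
write_clusters <- function(calls, bed_path = NULL, tsv_path = NULL) {
  cl <- calls$clusters
  if (!is.null(bed_path)) {
    bed <- data.frame(cl$chrom, cl$start - 1L, cl$end,
                      paste0(cl$sample_id, ":", cl$cluster_id),
                      pmin(round(-log10(cl$p_value), 2), 1000))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    write.table(cl, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cl)
}
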
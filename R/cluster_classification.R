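#' Strand-coordination cluster types
#'
#' Clusters are typed by the reference alleles mutated on the top (Watson)
#' strand, read 5' to 3'. A contiguous tract of ssDNA deaminated on one
#' strand leaves only mutated C's (top strand exposed) or only mutated G's
#' (bottom strand exposed); a switch from C's to G's marks the point where
#' the exposed strand flipped, e.g. at a resected double-strand break.
#'
#' @format Character vector of the nine type labels.
#' @export
CLUSTER_TYPES <- c("C_coordinated", "G_coordinated",
                   "C_coordinated_terminal_G", "G_coordinated_terminal_C",
                   "CG_single_switch_5pC", "CG_single_switch_5pG",
                   "CG_multiple_switch", "non_CG", "below_size_filter")

# The four classes displayed in type-distribution panels (terminal and
# coordinated pooled across C/G, switch subtypes pooled).
DISPLAY_CLASSES <- c("coordinated", "coordinated_terminal",
                     "single_switch", "multiple_switch")

type_to_class <- function(type) {
  c(C_coordinated = "coordinated", G_coordinated = "coordinated",
    C_coordinated_terminal_G = "coordinated_terminal",
    G_coordinated_terminal_C = "coordinated_terminal",
    CG_single_switch_5pC = "single_switch",
    CG_single_switch_5pG = "single_switch",
    CG_multiple_switch = "multiple_switch",
    non_CG = NA_character_, below_size_filter = NA_character_)[type]
}

#' Classify one mutation pattern
#'
#' `pattern` is the vector of mutated reference alleles of a cluster in
#' positional order (complex events contribute every member). Rules, in
#' order: any mutated A or T makes the cluster `non_CG`; fewer than
#' `min_mutations` C/G mutations is `below_size_filter` (a size filter —
#' only clusters with more than 3 mutations are used as ssDNA proxies, and
#' a single switch needs two runs of >= 2); otherwise the run structure of
#' the C/G string decides: one run is C- or G-coordinated; two runs with a
#' singleton end is coordinated-with-terminal (the lone opposite base may
#' sit at either the 5' or the 3' end); two runs of >= 2 each is a single
#' switch, subtyped by which base is 5'; three or more runs is multiple
#' switch.
#'
#' @param pattern Character vector of single bases (ref alleles, top
#'   strand, 5'->3').
#' @param min_mutations Minimum C/G mutation count for typing (default 4).
#' @return One of [CLUSTER_TYPES].
#' @export
classify_pattern <- function(pattern, min_mutations = 4L) {
  if (length(pattern) == 0) stop("empty mutation pattern")
  pattern <- toupper(pattern)
  if (!all(pattern %in% BASES)) stop("pattern must be A/C/G/T")
  if (any(pattern %in% c("A", "T"))) return("non_CG")
  if (length(pattern) < min_mutations) return("below_size_filter")
  r <- rle(pattern)
  nr <- length(r$values)
  if (nr == 1)
    return(if (r$values == "C") "C_coordinated" else "G_coordinated")
  if (nr == 2) {
    if (all(r$lengths >= 2))
      return(if (r$values[1] == "C") "CG_single_switch_5pC"
             else "CG_single_switch_5pG")
    # exactly one run is a singleton, necessarily at an end
    major <- r$values[which.max(r$lengths)]
    return(if (major == "C") "C_coordinated_terminal_G"
           else "G_coordinated_terminal_C")
  }
  "CG_multiple_switch"
}

#' Classify all clusters of a call set
#'
#' Adds to the cluster table: `type`, `class` (four-way display class, NA
#' for non-CG/undersized), and for single-switch clusters the switch
#' geometry (`left_arm_bp`, `right_arm_bp`: outermost-to-innermost span of
#' the 5' and 3' runs), and for coordinated-with-terminal clusters the
#' matched/nonmatched terminal distances used by the terminal-spacing
#' analysis.
#'
#' @param calls `cluster_calls` object from [detect_clusters()].
#' @param min_mutations Size filter passed to [classify_pattern()].
#' @return `calls` with an augmented `clusters` table (class
#'   `cluster_calls` preserved).
#' @export
classify_clusters <- function(calls, min_mutations = 4L) {
  stopifnot(inherits(calls, "cluster_calls"))
  cl <- calls$clusters
  n <- nrow(cl)
  cl$type <- character(n)
  cl$class <- NA_character_
  cl$left_arm_bp <- NA_real_
  cl$right_arm_bp <- NA_real_
  cl$nonmatched_dist <- NA_real_
  cl$matched_dist <- NA_real_
  for (i in seq_len(n)) {
    mem <- cluster_members(calls, cl$cluster_id[i])
    pat <- mem$ref
    ty <- classify_pattern(pat, min_mutations = min_mutations)
    cl$type[i] <- ty
    cl$class[i] <- unname(type_to_class(ty))
    if (ty %in% c("CG_single_switch_5pC", "CG_single_switch_5pG")) {
      r <- rle(pat)
      n1 <- r$lengths[1]
      cl$left_arm_bp[i] <- mem$pos[n1] - mem$pos[1]
      cl$right_arm_bp[i] <- mem$pos[length(pat)] - mem$pos[n1 + 1]
    }
    if (ty %in% c("C_coordinated_terminal_G", "G_coordinated_terminal_C")) {
      r <- rle(pat)
      npat <- length(pat)
      term_5p <- r$lengths[1] == 1           # lone base at the 5' end?
      if (term_5p) {
        cl$nonmatched_dist[i] <- mem$pos[2] - mem$pos[1]
        cl$matched_dist[i] <- mem$pos[npat] - mem$pos[npat - 1]
      } else {
        cl$nonmatched_dist[i] <- mem$pos[npat] - mem$pos[npat - 1]
        cl$matched_dist[i] <- mem$pos[2] - mem$pos[1]
      }
    }
  }
  calls$clusters <- cl
  calls$params$min_mutations <- min_mutations
  calls
}

#' Cluster-type distribution by stratum
#'
#' Counts and fractions of the four displayed classes (C/G-coordinated,
#' coordinated with a terminal base, single switch, multiple switch) per
#' stratum. Non-CG and undersized clusters are excluded from the
#' denominator.
#'
#' @param clusters Classified cluster table (from [classify_clusters()]
#'   `$clusters`).
#' @param strata Factor/character vector of stratum labels, one per cluster
#'   row, or NULL for a single stratum.
#' @return data.frame: stratum, class, n, fraction.
#' @export
type_distribution <- function(clusters, strata = NULL) {
  if (is.null(strata)) strata <- rep("all", nrow(clusters))
  stopifnot(length(strata) == nrow(clusters))
  keep <- !is.na(clusters$class)
  tab <- table(factor(strata[keep], levels = unique(strata)),
               factor(clusters$class[keep], levels = DISPLAY_CLASSES))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("stratum", "class", "n")
  tot <- stats::ave(out$n, out$stratum, FUN = sum)
  out$fraction <- ifelse(tot > 0, out$n / tot, NA_real_)
  out[order(match(out$stratum, unique(strata)),
            match(out$class, DISPLAY_CLASSES)), , drop = FALSE]
}

#' Single-switch polarity summary
#'
#' Fraction of single-switch clusters whose top-strand pattern reads
#' 5'C...3'G versus 5'G...3'C. A predominance of 5'C-3'G is the signature
#' expected from bidirectional 5'->3' resection around a break.
#'
#' @param clusters Classified cluster table.
#' @return list(n, frac_5pC_3pG, frac_5pG_3pC); fractions are NA when no
#'   single-switch clusters are present.
#' @export
switch_direction_summary <- function(clusters) {
  ss <- clusters$type[clusters$type %in%
                        c("CG_single_switch_5pC", "CG_single_switch_5pG")]
  n <- length(ss)
  if (n == 0) {
    warning("no single-switch clusters; fractions undefined")
    return(list(n = 0L, frac_5pC_3pG = NA_real_, frac_5pG_3pC = NA_real_))
  }
  fC <- mean(ss == "CG_single_switch_5pC")
  list(n = n, frac_5pC_3pG = fC, frac_5pG_3pC = 1 - fC)
}

#' Terminal-spacing analysis of coordinated-with-terminal clusters
#'
#' For each cluster carrying a single noncoordinated terminal base, compare
#' the distance from that base to its nearest cluster neighbor
#' (nonmatched) with the spacing at the opposite, coordinated end
#' (matched). If the lone terminal base were an unrelated mutation merely
#' co-located with a coordinated tract, nonmatched distances should run
#' larger than matched ones.
#'
#' @param clusters Classified cluster table (terminal types must carry the
#'   distance columns added by [classify_clusters()]).
#' @return list(nonmatched, matched, test = two-sided Wilcoxon rank-sum
#'   result), or NULL when no terminal-type clusters exist.
#' @export
terminal_distance_analysis <- function(clusters) {
  tt <- clusters[clusters$type %in% c("C_coordinated_terminal_G",
                                      "G_coordinated_terminal_C"), ]
  if (nrow(tt) == 0) return(NULL)
  test <- if (nrow(tt) >= 2)
    stats::wilcox.test(tt$nonmatched_dist, tt$matched_dist,
                       alternative = "two.sided", exact = FALSE)
  else NULL
  list(nonmatched = tt$nonmatched_dist, matched = tt$matched_dist,
       test = test)
}

#' Arm-length ratio dispersion of single-switch clusters
#'
#' The two arms of a single-switch cluster trace the two resected sides of
#' a break; symmetric resection gives log arm-length ratios near zero,
#' while asymmetric machinery inflates their spread. Returns the per-
#' stratum log-ratios and variances and, for each pair of strata, an
#' F test of variance equality.
#'
#' @param clusters Classified cluster table (single-switch rows used).
#' @param strata Stratum labels, one per cluster row, or NULL.
#' @return list(log_ratios = named list per stratum, variance = named
#'   numeric, tests = data.frame of pairwise F tests).
#' @export
arm_ratio_variance <- function(clusters, strata = NULL) {
  if (is.null(strata)) strata <- rep("all", nrow(clusters))
  ss <- clusters$type %in% c("CG_single_switch_5pC", "CG_single_switch_5pG")
  lr <- split(log(clusters$left_arm_bp[ss] / clusters$right_arm_bp[ss]),
              strata[ss])
  vars <- vapply(lr, stats::var, numeric(1))
  combs <- if (length(lr) >= 2) utils::combn(names(lr), 2) else NULL
  tests <- NULL
  if (!is.null(combs)) {
    tests <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      if (length(lr[[a]]) < 2 || length(lr[[b]]) < 2)
        return(data.frame(stratum_a = a, stratum_b = b,
                          var_ratio = NA_real_, p = NA_real_))
      ft <- stats::var.test(lr[[a]], lr[[b]])
      data.frame(stratum_a = a, stratum_b = b,
                 var_ratio = unname(ft$estimate), p = ft$p.value)
    }))
  }
  list(log_ratios = lr, variance = vars, tests = tests)
}
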
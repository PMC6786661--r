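CG_TYPES <- c("C_coordinated", "G_coordinated",
              "C_coordinated_terminal_G", "G_coordinated_terminal_C",
              "CG_single_switch_5pC", "CG_single_switch_5pG",
              "CG_multiple_switch")

#' Hypermutable-ssDNA estimate per sample
#'
#' Treats each CG cluster with more than 3 mutations as the footprint of a
#' persistent ssDNA tract and sums cluster lengths per genome:
#' `percent_ssDNA = 100 * sum(cluster length) / total_bases`, with
#' `total_bases` at the sample's ploidy (a diploid is measured against
#' twice the reference length). This is a minimum estimate: tracts that
#' escaped deamination leave no clusters.
#'
#' @param clusters Classified cluster table ([classify_clusters()]
#'   `$clusters`).
#' @param genome `genome_model` at the cohort's ploidy.
#' @param samples Sample ids to report (default: those present in
#'   `clusters`); samples without clusters report 0%.
#' @return data.frame per sample: sample_id, n_clusters (CG >3-mutation
#'   clusters), sum_cluster_length, percent_ssDNA, median_density
#'   (mutations/kb across those clusters).
#' @export
ssdna_fraction <- function(clusters, genome,
                           samples = unique(clusters$sample_id)) {
  stopifnot(inherits(genome, "genome_model"))
  if (!"type" %in% names(clusters))
    stop("clusters must be classified first (classify_clusters)")
  cg <- clusters[clusters$type %in% CG_TYPES, , drop = FALSE]
  if (length(samples) == 0)
    return(data.frame(sample_id = character(), n_clusters = integer(),
                      sum_cluster_length = numeric(),
                      percent_ssDNA = numeric(),
                      median_density = numeric()))
  out <- do.call(rbind, lapply(samples, function(s) {
    cs <- cg[cg$sample_id == s, , drop = FALSE]
    data.frame(sample_id = s,
               n_clusters = nrow(cs),
               sum_cluster_length = sum(cs$length),
               percent_ssDNA = 100 * sum(cs$length) / genome$total_bases,
               median_density = if (nrow(cs)) stats::median(
                 cluster_density(cs$n_mutations, cs$length)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Cluster mutation density
#' @param n_mutations Raw mutation count(s) of the cluster(s).
#' @param length Cluster length(s) in bp (bordering-mutation distance > 0).
#' @return Mutations per kb.
#' @export
cluster_density <- function(n_mutations, length) {
  if (any(length <= 0)) stop("cluster length must be positive")
  n_mutations * 1000 / length
}

#' Per-chromosome cluster distribution
#'
#' Counts clusters per chromosome and regresses count on chromosome length
#' to ask whether clusters spread across the genome in proportion to
#' chromosome size.
#'
#' @param clusters Cluster table (classified or not).
#' @param genome `genome_model`.
#' @return list(table = per-chromosome counts and lengths, fit = `lm`
#'   object or NULL, slope, intercept, p (slope test), degenerate
#'   (logical: all clusters on one chromosome or < 2 chromosomes)).
#' @export
chromosome_distribution <- function(clusters, genome) {
  stopifnot(inherits(genome, "genome_model"))
  counts <- table(factor(clusters$chrom, levels = genome$chrom_names))
  tab <- data.frame(chrom = genome$chrom_names,
                    length = as.numeric(genome$chrom_lengths),
                    n_clusters = as.integer(counts))
  degenerate <- length(genome$chrom_names) < 2 ||
    (nrow(clusters) > 0 && length(unique(clusters$chrom)) == 1)
  fit <- stats::lm(n_clusters ~ length, data = tab)
  # summary() warns on an exactly proportional fit; the slope test is
  # still what we report
  coefs <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(coefs) >= 2) coefs["length", "Pr(>|t|)"] else NA_real_
  list(table = tab, fit = fit,
       slope = unname(stats::coef(fit)["length"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       p = p, degenerate = degenerate)
}

#' Cohort-level cluster summaries
#'
#' Per-stratum incidence (% of isolates carrying at least one nonselected
#' cluster), cluster counts per isolate, and the standard comparisons:
#' pairwise Fisher exact tests on incidence and rank-sum tests on
#' per-isolate counts between strata.
#'
#' @param calls Classified `cluster_calls`.
#' @param metadata data.frame with `sample_id` plus grouping columns;
#'   every sample in `metadata` counts toward incidence even with zero
#'   clusters (sequenced isolates without clusters are informative).
#' @param group_col Name of the grouping column in `metadata`.
#' @param nonselected_only Count only nonselected clusters (default TRUE,
#'   matching incidence panels that exclude the reporter-selected cluster).
#' @return list(incidence = per-stratum table, per_isolate = counts per
#'   sample, incidence_tests, count_tests = pairwise comparison tables).
#' @export
cohort_summaries <- function(calls, metadata, group_col = "group",
                             nonselected_only = TRUE) {
  stopifnot(inherits(calls, "cluster_calls"),
            all(c("sample_id", group_col) %in% names(metadata)))
  cl <- calls$clusters
  if (nonselected_only && "selected" %in% names(cl))
    cl <- cl[!cl$selected, , drop = FALSE]
  n_by_sample <- table(factor(cl$sample_id, levels = metadata$sample_id))
  per_isolate <- data.frame(sample_id = metadata$sample_id,
                            group = metadata[[group_col]],
                            n_clusters = as.integer(n_by_sample))
  groups <- unique(per_isolate$group)
  incidence <- do.call(rbind, lapply(groups, function(g) {
    v <- per_isolate$n_clusters[per_isolate$group == g]
    data.frame(group = g, n_isolates = length(v),
               n_with_cluster = sum(v >= 1),
               percent_with_cluster = 100 * mean(v >= 1),
               mean_clusters = mean(v))
  }))
  pair_tests <- function(fun) {
    if (length(groups) < 2) return(NULL)
    combs <- utils::combn(as.character(groups), 2)
    do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      fun(per_isolate[per_isolate$group == a, "n_clusters"],
          per_isolate[per_isolate$group == b, "n_clusters"], a, b)
    }))
  }
  incidence_tests <- pair_tests(function(va, vb, a, b) {
    m <- matrix(c(sum(va >= 1), sum(va == 0), sum(vb >= 1), sum(vb == 0)),
                2, byrow = TRUE)
    data.frame(group_a = a, group_b = b,
               p = stats::fisher.test(m)$p.value)
  })
  count_tests <- pair_tests(function(va, vb, a, b) {
    p <- if (length(va) && length(vb) &&
             (stats::sd(c(va, vb)) > 0))
      stats::wilcox.test(va, vb, exact = FALSE)$p.value else 1
    data.frame(group_a = a, group_b = b, p = p)
  })
  list(incidence = incidence, per_isolate = per_isolate,
       incidence_tests = incidence_tests, count_tests = count_tests)
}
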
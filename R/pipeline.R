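#' Run the full analysis over a sample sheet
#'
#' Orchestrates detect -> classify -> enrich -> summarize for a cohort.
#' Each sample's catalog is loaded (VCF or MAF-like), clusters are called
#' and typed, motif enrichment is computed for the all/clustered/scattered
#' strata, and per-sample ssDNA estimates plus cohort tables are written
#' as tab-delimited files. Per-sample failures are caught and reported in
#' the index; the run continues. All outputs are deterministic for fixed
#' inputs.
#'
#' @param sample_sheet data.frame with columns `sample_id`, `path`
#'   (catalog file), optional `group` (stratum for cohort tables) and
#'   `ploidy` (default: genome's).
#' @param genome `genome_model` with sequences.
#' @param out_dir Output directory (created if needed).
#' @param reporter Optional selected-reporter interval
#'   ("chrII:start-end").
#' @param p_threshold,max_gap,max_distance Cluster-calling parameters, see
#'   [detect_clusters()].
#' @param min_mutations Classification size filter, see
#'   [classify_clusters()].
#' @param motif,window Enrichment parameters, see [motif_enrichment()].
#' @return Invisibly, a list with `calls`, `ssdna`, `enrichment`,
#'   `type_distribution`, `cohort`, `index` (per-sample status), and the
#'   output paths.
#' @export
run_pipeline <- function(sample_sheet, genome, out_dir,
                         reporter = NULL, p_threshold = 1e-4,
                         max_gap = 10L, max_distance = 10000L,
                         min_mutations = 4L, motif = "ytCa",
                         window = 20L) {
  stopifnot(is.data.frame(sample_sheet),
            all(c("sample_id", "path") %in% names(sample_sheet)))
  if (nrow(sample_sheet) == 0) stop("empty sample sheet")
  if (anyDuplicated(sample_sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  missing <- !file.exists(sample_sheet$path)
  if (any(missing))
    stop("catalog file(s) not found: ",
         paste(sample_sheet$path[missing], collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  index <- data.frame(sample_id = sample_sheet$sample_id,
                      status = "ok", n_mutations = NA_integer_,
                      n_dropped = NA_integer_, n_clusters = NA_integer_,
                      stringsAsFactors = FALSE)
  cats <- list()
  for (i in seq_len(nrow(sample_sheet))) {
    s <- sample_sheet$sample_id[i]
    res <- tryCatch(
      load_mutations(sample_sheet$path[i], sample_id = s, genome = genome),
      error = function(e) e)
    if (inherits(res, "error")) {
      index$status[i] <- conditionMessage(res)
      next
    }
    index$n_mutations[i] <- nrow(res)
    index$n_dropped[i] <- attr(res, "n_dropped")
    if (nrow(res)) cats[[s]] <- res
  }
  if (length(cats) == 0) stop("no loadable catalogs in sample sheet")
  mutations <- do.call(rbind, cats)
  calls <- detect_clusters(mutations, genome, p_threshold = p_threshold,
                           max_gap = max_gap, max_distance = max_distance,
                           reporter = reporter)
  calls <- classify_clusters(calls, min_mutations = min_mutations)
  n_cl <- table(factor(calls$clusters$sample_id,
                       levels = index$sample_id))
  index$n_clusters <- as.integer(n_cl)
  ssdna <- ssdna_fraction(calls$clusters, genome, samples = names(cats))
  enr <- stratified_enrichment(calls, genome, motif = motif,
                               window = window)
  strata <- if ("group" %in% names(sample_sheet))
    sample_sheet$group[match(calls$clusters$sample_id,
                             sample_sheet$sample_id)]
  else NULL
  tdist <- type_distribution(calls$clusters, strata)
  cohort <- if ("group" %in% names(sample_sheet))
    cohort_summaries(calls,
                     data.frame(sample_id = sample_sheet$sample_id,
                                group = sample_sheet$group),
                     group_col = "group")
  else NULL
  paths <- list(
    clusters_tsv = file.path(out_dir, "clusters.tsv"),
    clusters_bed = file.path(out_dir, "clusters.bed"),
    mutations_tsv = file.path(out_dir, "mutations_assigned.tsv"),
    ssdna_tsv = file.path(out_dir, "ssdna_summary.tsv"),
    enrichment_tsv = file.path(out_dir, "enrichment.tsv"),
    types_tsv = file.path(out_dir, "type_distribution.tsv"),
    index_tsv = file.path(out_dir, "index.tsv"))
  write_clusters(calls, bed_path = paths$clusters_bed,
                 tsv_path = paths$clusters_tsv)
  write.table(calls$mutations, paths$mutations_tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ssdna, paths$ssdna_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(enr, paths$enrichment_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tdist, paths$types_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(index, paths$index_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(cohort)) {
    paths$cohort_tsv <- file.path(out_dir, "cohort_incidence.tsv")
    write.table(cohort$incidence, paths$cohort_tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(list(calls = calls, ssdna = ssdna, enrichment = enr,
                 type_distribution = tdist, cohort = cohort,
                 index = index, paths = paths))
}
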
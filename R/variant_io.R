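#' @importFrom utils read.delim write.table head
NULL

BASES <- c("A", "C", "G", "T")

# Default column map for MAF-like tab-delimited catalogs.
maf_default_columns <- c(sample_id = "Tumor_Sample_Barcode",
                         chrom     = "Chromosome",
                         pos       = "Start_position",
                         ref       = "Reference_Allele",
                         alt       = "Tumor_Seq_Allele2")

#' Validate and canonicalize a mutation catalog
#'
#' The canonical catalog is a data.frame with columns `sample_id`, `chrom`,
#' `pos` (1-based), `ref`, `alt` — single-base substitutions only, reported
#' on the forward (Watson) strand. Records are sorted by
#' (sample_id, chrom, pos); fully identical records are an error by default
#' (they would silently double-count in the cluster statistic) or
#' deduplicated on request. Distinct alternate alleles at one position
#' (multi-allelic splits) survive validation but are rejected by
#' [detect_clusters()], which requires one mutation per position.
#'
#' @param x data.frame with the five canonical columns.
#' @param genome Optional `genome_model`; when given, chromosome names and
#'   positions are checked against it.
#' @param on_duplicate "error" or "dedupe" (first record kept).
#' @return The validated, sorted data.frame.
#' @export
validate_mutations <- function(x, genome = NULL,
                               on_duplicate = c("error", "dedupe")) {
  on_duplicate <- match.arg(on_duplicate)
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$sample_id <- as.character(x$sample_id)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$ref <- toupper(as.character(x$ref))
  x$alt <- toupper(as.character(x$alt))
  bad <- which(!(x$ref %in% BASES) | !(x$alt %in% BASES) | x$ref == x$alt |
                 is.na(x$pos) | x$pos < 1)
  if (length(bad))
    stop("invalid SNV record(s) at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  if (!is.null(genome)) {
    unk <- setdiff(unique(x$chrom), genome$chrom_names)
    if (length(unk))
      stop("chromosome(s) not in genome model: ", paste(unk, collapse = ", "))
    over <- x$pos > genome$chrom_lengths[x$chrom]
    if (any(over))
      stop("position beyond chromosome end at row(s): ",
           paste(head(which(over), 5), collapse = ", "))
  }
  key <- paste(x$sample_id, x$chrom, x$pos, x$ref, x$alt)
  if (anyDuplicated(key)) {
    if (on_duplicate == "error")
      stop("duplicate record(s), e.g. ", key[duplicated(key)][1])
    x <- x[!duplicated(key), ]
  }
  x <- x[order(x$sample_id, x$chrom, x$pos), ]
  rownames(x) <- NULL
  x
}

#' Read a mutation catalog from VCF or a MAF-like table
#'
#' VCF rows are split on multi-allelic ALT; any record whose REF or ALT is
#' not a single A/C/G/T base (indels, MNVs) is dropped and counted. MAF-like
#' input is a tab-delimited table read through a configurable column map;
#' coordinates are taken as 1-based in both formats.
#'
#' @param path Input file.
#' @param format "auto" (by extension), "vcf" or "maf".
#' @param sample_id Sample name to assign when the file itself carries none
#'   (single-sample VCF); ignored when the MAF column map supplies one.
#' @param genome Optional `genome_model` for coordinate validation.
#' @param column_map Named character vector mapping canonical names
#'   (`sample_id`, `chrom`, `pos`, `ref`, `alt`) to file column titles for
#'   MAF-like input. `sample_id` may be omitted from the map if `sample_id=`
#'   is given.
#' @param on_duplicate Passed to [validate_mutations()].
#' @return Canonical catalog data.frame; the number of dropped non-SNV rows
#'   is attached as attribute `n_dropped` and reported via `message()`.
#' @export
load_mutations <- function(path, format = c("auto", "vcf", "maf"),
                           sample_id = NULL, genome = NULL,
                           column_map = maf_default_columns,
                           on_duplicate = c("error", "dedupe")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "maf"
  }
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0) {
      out <- empty_catalog()
      attr(out, "n_dropped") <- 0L
      return(out)
    }
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    rep_i <- rep(seq_len(nrow(fix)), lengths(alts))
    df <- data.frame(sample_id = if (is.null(sample_id))
      tools_file_sans_ext(basename(path)) else sample_id,
      chrom = fix$CHROM[rep_i],
      pos = as.integer(fix$POS[rep_i]),
      ref = toupper(fix$REF[rep_i]),
      alt = toupper(unlist(alts)),
      stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "#")
    cm <- column_map
    if (is.null(sample_id) && !("sample_id" %in% names(cm)))
      stop("MAF column map lacks sample_id and no sample_id= given")
    need <- cm[setdiff(names(cm), if (is.null(sample_id)) character()
                       else "sample_id")]
    miss <- setdiff(unname(need), names(tab))
    if (length(miss))
      stop("MAF-like file lacks column(s): ", paste(miss, collapse = ", "))
    pos_raw <- tab[[cm[["pos"]]]]
    pos_num <- suppressWarnings(as.numeric(pos_raw))
    if (anyNA(pos_num))
      stop("malformed position at line ",
           which(is.na(pos_num))[1] + 1L, " of ", path)
    df <- data.frame(
      sample_id = if (!is.null(sample_id)) sample_id
                  else as.character(tab[[cm[["sample_id"]]]]),
      chrom = as.character(tab[[cm[["chrom"]]]]),
      pos = as.integer(pos_num),
      ref = toupper(as.character(tab[[cm[["ref"]]]])),
      alt = toupper(as.character(tab[[cm[["alt"]]]])),
      stringsAsFactors = FALSE)
  }
  snv <- df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt
  n_dropped <- sum(!snv)
  if (n_dropped > 0)
    message(n_dropped, " non-SNV record(s) dropped from ", basename(path))
  out <- validate_mutations(df[snv, , drop = FALSE], genome = genome,
                            on_duplicate = on_duplicate)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a catalog as a MAF-like tab-delimited table
#'
#' Uses the same column titles [load_mutations()] reads by default, so a
#' write/read round trip reproduces the catalog exactly.
#'
#' @param x Canonical catalog data.frame.
#' @param path Output path.
#' @param column_map Canonical-to-file column name map.
#' @return `path`, invisibly.
#' @export
write_mutations_maf <- function(x, path, column_map = maf_default_columns) {
  x <- validate_mutations(x)
  out <- x[names(column_map)]
  names(out) <- unname(column_map)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a catalog as a minimal VCF
#'
#' One sample per file; emits VCFv4.2 fixed columns only.
#'
#' @param x Canonical catalog for a single sample.
#' @param path Output path.
#' @param genome Optional `genome_model` used to emit contig header lines.
#' @return `path`, invisibly.
#' @export
write_mutations_vcf <- function(x, path, genome = NULL) {
  x <- validate_mutations(x)
  if (length(unique(x$sample_id)) > 1)
    stop("write_mutations_vcf() writes one sample per file")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(genome))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", genome$chrom_names,
                       as.integer(genome$chrom_lengths)), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(x))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       x$chrom, x$pos, x$ref, x$alt), con)
  invisible(path)
}

empty_catalog <- function() {
  data.frame(sample_id = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             stringsAsFactors = FALSE)
}

# tools::file_path_sans_ext without importing tools
tools_file_sans_ext <- function(x) sub("\\.(vcf|vcf\\.gz|tsv|maf|txt)$", "",
                                       x, ignore.case = TRUE)
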
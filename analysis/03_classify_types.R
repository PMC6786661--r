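#!/usr/bin/env Rscript
# Type every CG cluster (>3 mutations) by its top-strand run structure and
# summarize: type distributions per cohort, single-switch polarity,
# terminal-spacing comparison for coordinated-with-terminal clusters, and
# arm-ratio dispersion of single-switch clusters. Outputs under
# results/types/.

suppressMessages(library(hypermut))
simdir <- "results/sim"
out <- "results/types"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
sheet <- read.delim(file.path(simdir, "samples.tsv"))
genome <- load_genome(file.path(simdir, "genome.fa"))
muts <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i)
  load_mutations(sheet$path[i], sample_id = sheet$sample_id[i],
                 genome = genome)))
calls <- classify_clusters(detect_clusters(muts, genome,
                                           reporter = "chrII:33000-48000"))
cl <- calls$clusters
cl$group <- sheet$group[match(cl$sample_id, sheet$sample_id)]
write.table(cl, file.path(out, "clusters_classified.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

td <- type_distribution(cl, cl$group)
write.table(td, file.path(out, "type_distribution.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("cluster-type fractions by cohort (CG clusters with >3 mutations):\n")
for (grp in unique(td$stratum)) {
  r <- td[td$stratum == grp, ]
  cat(sprintf("  %-20s %s\n", grp,
              paste(sprintf("%s %.2f", r$class, r$fraction),
                    collapse = ", ")))
}

mech_groups <- grep("^mech_", unique(cl$group), value = TRUE)
for (grp in mech_groups) {
  s <- suppressWarnings(switch_direction_summary(cl[cl$group == grp, ]))
  if (s$n > 0)
    cat(sprintf("%s: %d single-switch clusters, %.0f%% 5'C-3'G\n",
                grp, s$n, 100 * s$frac_5pC_3pG))
}

tda <- terminal_distance_analysis(cl)
if (!is.null(tda) && !is.null(tda$test))
  cat(sprintf("terminal spacing: median nonmatched %0.f bp vs matched %0.f bp (rank-sum p = %.3g)\n",
              median(tda$nonmatched), median(tda$matched),
              tda$test$p.value))

arm <- arm_ratio_variance(cl, cl$group)
if (length(arm$variance))
  cat("log arm-ratio variance by cohort:",
      paste(sprintf("%s %.2f", names(arm$variance), arm$variance),
            collapse = ", "), "\n")
cat("tables written under", out, "\n")
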
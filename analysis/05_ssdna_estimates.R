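#!/usr/bin/env Rscript
# Hypermutable-ssDNA estimates per isolate (sum of CG >3-mutation cluster
# lengths over genome size), cluster densities, the per-chromosome
# distribution regression, and cohort incidence tables. Outputs under
# results/ssdna/.

suppressMessages(library(hypermut))
simdir <- "results/sim"
out <- "results/ssdna"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
sheet <- read.delim(file.path(simdir, "samples.tsv"))
genome_hap <- load_genome(file.path(simdir, "genome.fa"), ploidy = 1)
genome_dip <- load_genome(file.path(simdir, "genome.fa"), ploidy = 2)
muts <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i)
  load_mutations(sheet$path[i], sample_id = sheet$sample_id[i],
                 genome = genome_hap)))
calls <- classify_clusters(detect_clusters(muts, genome_hap,
                                           reporter = "chrII:33000-48000"))
cl <- calls$clusters
grp <- function(s) sheet$group[match(s, sheet$sample_id)]

# diploid isolates are measured against 2x the reference length
dip <- sheet$sample_id[grepl("^dip", sheet$sample_id)]
hap <- sheet$sample_id[grepl("^(hap|mech)", sheet$sample_id)]
ss <- rbind(ssdna_fraction(cl[cl$sample_id %in% dip, ], genome_dip,
                           samples = dip),
            ssdna_fraction(cl[cl$sample_id %in% hap, ], genome_hap,
                           samples = hap))
ss$group <- grp(ss$sample_id)
write.table(ss, file.path(out, "ssdna_per_isolate.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (g in unique(ss$group)) {
  v <- ss[ss$group == g, ]
  cat(sprintf("  %-16s median %.2f%% ssDNA, median summed cluster length %6.0f kb\n",
              g, median(v$percent_ssDNA),
              median(v$sum_cluster_length) / 1000))
}

cd <- chromosome_distribution(cl[cl$sample_id %in% dip & !cl$selected, ],
                              genome_hap)
write.table(cd$table, file.path(out, "clusters_per_chromosome.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("clusters vs chromosome length: slope %.3g per bp, p = %.3g%s\n",
            cd$slope, cd$p,
            if (cd$degenerate) " (degenerate)" else ""))

meta <- data.frame(sample_id = sheet$sample_id, group = sheet$group)
coh <- cohort_summaries(calls, meta, group_col = "group")
write.table(coh$incidence, file.path(out, "cohort_incidence.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("incidence of >=1 nonselected cluster per isolate:\n")
print(coh$incidence, row.names = FALSE)
gamma_vs_null <- coh$incidence_tests[
  coh$incidence_tests$group_a == "diploid_gamma" &
    coh$incidence_tests$group_b == "diploid_no_gamma", ]
if (nrow(gamma_vs_null))
  cat(sprintf("gamma vs no-gamma incidence, Fisher exact p = %.3g\n",
              gamma_vs_null$p))
cat("tables written under", out, "\n")
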
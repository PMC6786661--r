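# External data drop-in

This directory ships empty. Two acceptance tests recompute published
per-isolate cluster statistics and enrichment bands from the original
experiment's supplementary mutation calls, which are distributed with the
source publication and not redistributed here. To enable them, place:

- `s1_data_mutations.tsv` — the per-isolate mutation calls as a MAF-like
  tab-delimited table with columns `Tumor_Sample_Barcode`, `Chromosome`,
  `Start_position`, `Reference_Allele`, `Tumor_Seq_Allele2` (1-based
  coordinates, top-strand alleles);
- `reference.fa` — the matching reference genome FASTA (needed only for
  the motif-enrichment band check).

Everything else in the test suite and in `scripts/acceptance.R` generates
its inputs in code.
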
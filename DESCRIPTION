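Package: hypermut
Title: Clustered Hypermutation Analysis and DSB-Repair ssDNA Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of clustered hypermutation
    (kataegis) in whole-genome somatic mutation catalogs. Implements the
    negative-binomial cluster statistic for calling mutation clusters
    against a genome-wide background rate, a strand-coordination taxonomy
    for CG clusters (C/G-coordinated, terminal, single-switch,
    multiple-switch), APOBEC motif enrichment with local 41-nucleotide
    context normalization, and hypermutable single-stranded DNA (ssDNA)
    estimates from cluster lengths. Includes a mechanistic simulator of
    ssDNA formed during double-strand-break repair (bidirectional
    resection, unidirectional resection, and break-induced replication)
    that emits strand-specific cytosine-deamination catalogs with ground
    truth, so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
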
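---
title: "Detecting and interpreting clustered hypermutation from DSB-repair ssDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and interpreting clustered hypermutation from DSB-repair ssDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypermut)
```

## The model

Single-stranded DNA exposed during double-strand-break (DSB) repair is
the substrate of APOBEC cytidine deaminases. Each deamination converts a
cytosine of the exposed strand to uracil; without uracil glycosylase the
lesion replicates into a fixed C→T change on that strand. Reading the
top (Watson) strand, deamination of the top strand appears as C→T and
deamination of the bottom strand as G→A. A contiguous ssDNA tract
therefore produces a *strand-coordinated* cluster, and the geometry of
strand exposure around a break is recoverable from the cluster's run
structure:

* 5'→3' resection on **both** sides of a break exposes the top strand on
  the left and the bottom strand on the right, so the cluster switches
  once, C-runs 5' of G-runs (`CG_single_switch_5pC`);
* one-ended resection or break-induced replication exposes a single
  strand, giving an all-C or all-G cluster, the side chosen by which
  break end initiates.

Every analysis in this package is a consequence of that model: cluster
calling finds the tracts, classification reads back the exposure
geometry, motif enrichment confirms the deaminase origin, and the summed
cluster length bounds the amount of persistent ssDNA from below.

### Cluster calling

Mutations of one sample closer than 10 bp are collapsed into a single
*complex event*, because one mutagenic encounter can leave several
nearby changes; the collapsed event counts once everywhere. Collapsed
events chained at inter-event (nearest-edge) distances up to 10 kb form
candidate groups. For a group of $k$ events spanning $x$ bases the
probability of so dense an accumulation under a uniform per-base
mutation probability $\pi$ is the negative-binomial tail

$$p=\sum_{j=0}^{x-k}\binom{k+j-2}{j}(1-\pi)^j\pi^{k-1},$$

i.e. the probability that the $(k-1)$-th further mutation arrives within
$x-1$ or fewer bases. $\pi$ is the sample's total collapsed events over
the genome's total bases at the sample's ploidy — consistent with $k$,
which also counts complexes once. Groups with $p\le 10^{-4}$ are
reported as clusters; the threshold is used exactly, with no
multiple-testing correction, so that per-genome false calls scale with
the number of tested groups (see *Limitations*).

Two span conventions coexist deliberately. The statistic uses
$x = \text{last} - \text{first} + 1$ bases, matching the
"$k-1$ mutations in $x-1$ or fewer bp" indexing of the formula; the
reported cluster *length* is the distance between the bordering
mutations (no $+1$), which is the quantity summed into ssDNA estimates.

### Classification

Clusters are typed from the reference alleles of their members in
positional order on the top strand. Any mutated A or T excludes the
cluster from CG typing (`non_CG`); a CG cluster needs more than 3
mutations to be typed (`below_size_filter` otherwise) — read strictly as
≥4, since a single switch needs two runs of ≥2. The run structure then
decides: one run is coordinated; two runs with a lone base at either end
is coordinated-with-terminal; two runs of ≥2 each is a single switch,
subtyped by the 5' base; three or more runs is multiple-switch. Complex
events contribute each member to the pattern in positional order, so a
mixed C/G complex can make a cluster multiple-switch-eligible like any
other alternation; a terminal base that is itself a complex member is
tolerated. Mutation identity uses the reference allele only (any C→N is
a "mutated C"): in the experimental setting nearly all changes are
C→T/G→A, but the rule must be total.

Two diagnostics probe whether cluster sub-structures are real:
`terminal_distance_analysis()` compares the spacing of the lone
noncoordinated terminal base against the opposite, coordinated end
(a lone base merely co-located with a tract tends to sit farther away),
and `arm_ratio_variance()` compares the dispersion of
$\log(\text{left arm}/\text{right arm})$ of single-switch clusters
between strata (asymmetric resection machinery inflates it).

### Motif enrichment

For a signature motif such as the A3A-like `ytCa` (mutated base
capitalized; IUPAC: y = C/T, r = A/G, w = A/T), enrichment compares the
motif fraction among mutations with the motif fraction in the local
sequence context:

$$E=\frac{\text{mut}(\text{motif})\times\text{ctx}(C)}
        {\text{mut}(C{\to}T)\times\text{ctx}(\text{motif})}.$$

Qualifying mutations are all C→T changes plus G→A as the bottom-strand
complement, each checked against the motif (or its reverse complement)
at its genomic position. Context is counted in a window of ±20 bp around
every qualifying site — 41 nt total — pooling motif occurrences on both
strands and C+G bases; windows truncate at chromosome ends rather than
being discarded, and N bases never match. Using local windows rather
than whole-genome composition absorbs regional composition and
accessibility biases. Significance is a one-sided Fisher exact test of
the mutation tally against the context tally, reported uncorrected; the
convenience threshold for calling a set "enriched" (E > 2, p < 0.05) is
a package default, not a measured constant.

### ssDNA estimates

`percent_ssDNA` is $100\times$ the summed length of CG clusters with >3
mutations over the genome's total bases. Ploidy scales the denominator
only — a diploid is two unphased copies, $2\times$ the reference length,
ignoring loss of heterozygosity. The estimate is a *minimum*: tracts
that escaped deamination, or were deaminated below the detection
threshold, leave nothing to sum.

## The simulator

`simulate_catalog()` generates catalogs with ground truth under the
three exposure mechanisms. Per break: a mechanism is drawn from
`mechanism_mix`; per-side tract lengths are lognormal
(`tract_meanlog = log(5000)`, `tract_sdlog = 0.5` by default — median
5 kb, the order of observed cluster-length medians; BIR tails default to
a 10 kb median); exposed-strand cytosines deaminate with probability
0.055 at motif-matching sites and 1/20 of that elsewhere. On a GC-0.38
genome those defaults put roughly 0.9 motif sites plus 18 other C's per
100 bp of tract in play, i.e. about one mutation per kb of tract — the
density observed in real clusters. Background SNVs are uniform in
position and spectrum at `2.5e-6`/bp (≈30 per haploid 12-Mb genome).
The default `mechanism_mix` is uniform over the three mechanisms: the
source experiments do not fix per-mechanism frequencies, and a neutral
default keeps cohort simulations from prejudging the geometry readout.

What the generator *does not* emulate, and what passing tests therefore
do not show about real data: sequence-context biases beyond the single
motif preference, replication-timing and transcription covariates,
joint-molecule repair products, gene conversion, copy-number change, and
selection. Multiple-switch clusters arise in simulation only through
chance adjacency of independent events or unphased merging of homolog
copies (`copies = 2`), which is also the confounder such clusters face
in real diploid data.

## Numerical choices

* The cluster P-value is summed by multiplicative recurrence outward
  from the largest in-range term of the negative-binomial pmf, scaled so
  a single `exp`/`log` round trip touches the result; terms below
  $10^{-17}$ of the running sum are dropped. This holds relative error
  near $10^{-12}$ up to $k\sim 10^3$ and spans of tens of kb; values
  whose true magnitude is below the smallest normal double underflow, as
  they must.
* Distances: "<10 bp" collapses and "≤10 kb" chains, both exact integer
  comparisons; a 10-bp gap is two events, a 10,000-bp gap is one group.
* Degenerate inputs fail loudly: duplicate records, two mutations at one
  position in one sample, $\pi\notin(0,1)$, empty clusters, zero-length
  clusters.
* Ties in rank-sum comparisons use the normal approximation
  (`exact = FALSE`).

## Problem sizes

The test suite and `scripts/acceptance.R` choose sizes that make the
statistical assertions sharp while staying lightweight: 1,000 random
$(k,x,\pi)$ triples against the independent negative-binomial CDF;
$10^4$ null catalogs of 30 mutations on a 12.07-Mb genome for the
false-call rate; 110 events per mechanism spread over $4\times 12$ Mb
with 8-kb median tracts for mechanism recovery — spacing chosen so
independently repaired breaks rarely fall within one 10-kb chaining
distance, since chained neighbors classify as multiple-switch and would
measure crowding rather than geometry; and a 12-isolate simulated
diploid cohort for the ssDNA, incidence and enrichment summaries.

## Limitations

* The $10^{-4}$ threshold controls the per-group error, not the
  per-genome error: a genome with $n$ mutations carries roughly $n$
  testable gaps, so uniform catalogs still yield occasional 2–3-mutation
  false clusters at a few-per-thousand-genomes rate. Interpreting small
  clusters individually, rather than in cohort contrasts, should respect
  that.
* Grouping is single-pass maximal chaining; a non-significant group is
  not re-searched for significant sub-windows. Dense tracts embedded in
  diffuse mutation neighborhoods can thus be absorbed into a
  non-significant group.
* Whether $\pi$ should exclude repetitive or organellar regions is
  unresolved; the whole nuclear genome is used.
* Classification reads only the mutated-base sequence; it does not
  attempt per-cluster mechanism assignment, which is meaningful only at
  the distribution level.
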
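---
title: "Differential genic profiling of cell-free eccDNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential genic profiling of cell-free eccDNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difcir)
```

## The problem

Extrachromosomal circular DNA (eccDNA) is excised from chromosomes and, in
blood plasma, circulates cell-free. Split sequencing reads spanning a circle
junction locate each circle as a genomic interval with a support count.
Classical circulome comparators — the number of circles per sample and their
length distribution — are insensitive because they pool all loci into one
number. The gene-centric alternative implemented here asks instead *which
genes* produce more circles in one condition than another: it aggregates
split reads per gene into produced-per-gene-circle (PpGC) scores and selects
differentially produced per-gene eccDNAs (DPpGCs) with the DifCir procedure,
then characterises the selected genes by chromosome landscape, chromosomal
fragile sites (CFSs), GWAS traits and cross-species overlap.

## Preprocessing circle tables

Input is one table per sample of circle intervals (0-based half-open, BED
convention throughout) with split-read counts, the output format of
split-read circle callers. Two cleaning steps precede quantification:

* **Coalescing.** Callers emit near-duplicate calls whose breakpoints
  jitter by a few bp. Records on one chromosome are linked when *both*
  start and end coordinates differ by less than `d_min` (default 10 bp);
  clusters are the transitive closure of this relation (single linkage).
  Each cluster becomes one record with the coordinates of its
  best-supported member (ties: smallest start, then end) and the summed
  split reads, so total support is conserved exactly. The start-AND-end
  rule matches breakpoint jitter; linking on a single coordinate would
  merge distinct circles sharing one breakpoint. Coalescing is per sample:
  merging across samples would conflate biological replicates.
* **Filtering**, in order after merging: drop records with fewer than 2
  post-merge split reads (singleton junction reads are unreliable), drop
  excluded chromosomes (default `chrM`, which is circular and dominates
  otherwise), and drop circles longer than 10 kb — the small-circle
  cutoff, applied globally to quantification and length statistics; a
  circle of exactly 10,000 bp is kept (strict `>` comparison).

"Unique eccDNAs" per sample means post-merge, post-filter records; group
summaries report mean ± sem (sd/√n). Group counts are compared with the
two-sided Wilcoxon rank-sum test — exact by permutation when the combined
sample size is ≤ 16 and tie-free, otherwise the normal approximation with
tie and continuity correction (the exactness threshold and the continuity
correction are implementation choices) — and by the fold of means
mean(x)/mean(y). Length distributions are summarised per sample as the
cumulative percentage of circle lengths at a set of bin edges, with a group
mean curve and per-bin sd band; zero-circle samples have no defined curve
and are skipped with a warning.

## PpGC quantification

A circle contributes its full split-read count to **every** gene it
overlaps by at least 1 bp (half-open intersection, identical to
`bedtools intersect` semantics); nothing is apportioned between genes,
because a circle carrying a fragment of two genes is evidence of excision
at both. Gene-level models only: isoforms of one gene count once. The
unscaled PpGC of gene *i* in sample *s* is that sum. Longer genes intersect
more circles by chance, so each PpGC is scaled by `L_Max / L_i` where
`L_i` is the gene length and `L_Max` the longest gene found in the dataset;
finally values are equalized as `log2(scaled + 1)` so zero counts map to
zero and the differential test operates on log2 fold changes.

`L_Max` is dataset-relative. By default it is taken over genes with at
least one split read ("found in the dataset"); a switch (`l_max_mode =
"all"`) takes it over all annotated genes. PpGC values are therefore
comparable only within one run, and the run manifest records `L_Max`.

## The DifCir call

For two groups A and B (each ≥ 2 samples), every gene with a nonzero raw
count in at least one sample gets a classical two-sample Student's t-test
(pooled variance, two-sided) on its PpGC values; the equal-variance form is
the default because that is what the method's name announces, with a Welch
switch (`welch = TRUE`). A gene is a DPpGC when `|Δ| ≥ θ` and `p ≤ α`,
where `Δ = mean_A − mean_B` is the log2 fold change, with inclusive
comparisons so boundary cases are kept; defaults θ = 1, α = 0.05. No
multiple-testing correction is applied by default, matching the raw-p
usage the thresholds were published with; `adjust = "BH"` is available.
Direction is the sign of Δ; both directions are always reported. Within a
direction, genes are ranked by ascending p, ties by descending `|Δ|`, then
symbol. Degenerate genes (zero variance in both groups) bypass the t
statistic: p is set to 0 when the means differ (and the gene is flagged)
and to 1 when they do not.

## Enrichment statistics

All over-representation uses the **upper-tail hypergeometric mid-p**,
`P(X > k) + 0.5·P(X = k)`: the half-weight on the observed outcome
compensates the conservativeness of discrete tails. Only the enrichment
tail is tested; depletion is reported descriptively (negative Δc below),
not tested. Stars summarise significance by decade: `*` for
0.01 ≥ p > 0.001, `**` for 0.001 ≥ p > 0.0001, and so on; nothing above
0.01.

* **Chromosome landscape.** For chromosome *c*,
  `Δc = 100·(Nd_c/N_c − Nd_g/N_g)` with Nd_c the DPpGC genes on *c*, N_c
  the eccDNAs on *c*, and Nd_g, N_g the genome-wide totals; the identity
  `Σ_c N_c·Δc = 0` holds by construction and is verified in the tests.
  The companion mid-p uses the same counts (population N_g, successes
  N_c, draws Nd_g, observed Nd_c). The formula deliberately mixes units —
  genes over circle counts — as published; chromosomes with no eccDNA are
  omitted. eccDNAs are counted across all samples of the cohort (whether
  the original analysis used unique loci instead is not decidable; counts
  across samples weight chromosomes by evidence).
* **Gene-set over-representation** (fragile sites, GMT collections): the
  universe is the eccDNA-producing genes of the comparison (nonzero raw
  PpGC) — the natural background because only such genes can be called;
  hits are the up-DPpGC list; the reported percentage is `100·k/|hits|`.
* **Fragile sites** are read from a HumCFS-style table with the inducing
  agent (aphidicolin, folic acid, BrdU, 5-azacytidine, distamycinA); the
  pooled category is the union over the five agents. Cross-species
  queries go through a HomoloGene-style symbol map; all symbol matching
  through the map is case-insensitive (mouse `Dab1` vs human `DAB1`).
* **GWAS traits** are matched as exact strings (catalog trait labels are
  controlled vocabulary); multi-gene mapped-gene cells split on commas,
  semicolons and `" - "`.

## The synthetic cohort generator

The generator provides ground-truth cohorts in the exact input format of
the pipeline. It emulates the study design the pipeline targets — and
nothing finer: 12 control vs 11 knockout plasma samples; Poisson(300)
background circles per sample placed uniformly on the genome (chromosome
chosen proportional to length); circle lengths from a truncated-normal
mixture at 180 bp (sd 40) and 360 bp (sd 60), weights 0.7/0.3 on
[50, 10000] bp, reproducing the sub-kilobase nucleosome-footprint profile
of plasma eccDNA without claiming to match any exact curve; split reads
2 + Poisson(1); and with probability 0.1 a circle emitted twice with both
breakpoints jittered by < `d_min`, exercising the coalescer. Knockout
samples add, for each of 20 planted effect genes, Poisson(λ_i·m) circles
inside the gene body, where λ_i = background_rate·L_i/genome_length is the
gene's background expectation and m = 8 the effect multiplier — so m reads
directly as an excision-rate fold change. A synthetic fragile-site table
labels 15% of genes, drawn independently of the effect genes, so CFS
enrichment is null by construction.

The synthetic genome is scaled to desk size: 5 chromosomes × 40
non-overlapping genes with log-uniform lengths between 10 and 100 kb
(≈ 12 Mb total). This keeps the per-gene background expectation near
0.5–1 circle per sample — comparable to the sparse per-gene evidence in
real plasma cohorts — while the whole pipeline runs in seconds. What the
simulator does **not** model: sequencing-depth differences, mapper error,
GC or accessibility bias along the genome, gene-density structure,
library-protocol (tagmentation vs rolling-circle) effects beyond a
manifest label, and inter-sample overdispersion beyond Poisson. Passing
recovery tests therefore demonstrate the statistical machinery under the
declared generative model, not performance on real libraries.

All randomness flows from one integer seed; per-sample substreams are
derived by counter offset, so cohorts are byte-reproducible and
insensitive to evaluation order.

Under these study conditions the DifCir call attains sensitivity ≈ 1 for
the planted genes with a false-discovery proportion around 0.15–0.19
(averaged over 10 seeds) — the expected behaviour of raw-p selection at
α = 0.05 over ~200 candidate genes; enabling the Benjamini–Hochberg option
trades some of that FDP for sensitivity.

## Numerical choices and degenerate inputs

* Coordinates are integer bp; coalescing uses strict `<` on both deltas,
  so `d_min = 0` disables merging.
* `log2(x + 1)` maps zero raw counts to exactly 0; the PpGC matrix keeps
  all-zero genes (flagged droppable) but DifCir excludes them.
* Star assignment guards decade boundaries against floating-point (an
  additive 1e-9 nudge on −log10 p before flooring).
* Mid-p queries validate `0 ≤ k ≤ min(n, K)`, `n ≤ N`, `K ≤ N` and reject
  violations rather than clamping.
* Empty hit lists yield percentage 0, mid-p 1, and a `flagged` marker
  rather than an error, so a null comparison propagates visibly through
  the summary table.

## Reproducing the analyses

The `analysis/` scripts run the full workflow on the synthetic cohort
(`01_simulate.R` → `04_enrichment.R`), writing TSVs under `results/`.
The problem sizes used there and in the test suite (200-gene genomes,
23-sample cohorts, 10-seed recovery averages, 2,000-draw calibration)
were chosen as the smallest sizes at which the recovery and calibration
properties are stable; all are regenerated from code at run time.
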
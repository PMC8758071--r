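---
title: "Linking gene duplication history to genic GC content and methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking gene duplication history to genic GC content and methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syngc)
```

## The question and the approach

Monocot grasses carry a bimodal distribution of genic GC content that most
eudicots lack: one class of genes with third-codon-position GC (GC3) near
90–94% and another with a mode near 40%. A candidate explanation couples
three observations. Genes that stay *syntenic* — conserved in gene order
against distantly related genomes — have rarely been duplicated away from
their ancestral locus. Genes that duplicate to new loci (dispersed
duplication, often followed by loss of the original copy) become
non-syntenic, are frequent targets of siRNA-directed cytosine methylation,
and methylated cytosines deaminate to thymine at elevated rates while
reduced gene conversion no longer pushes A:T back toward G:C. Over long
times this mutational environment erodes GC at the least-constrained
sites, the third codon position, most visibly near the 5' end of genes.

`syngc` implements the complete chain of measurements this hypothesis
needs, each testable in isolation and end-to-end:

1. **Synteny** — chain homolog anchor pairs into collinear blocks of at
   least 7 gene pairs and classify genes as syntenic/non-syntenic.
2. **GC3-50** — GC at the third position of the first 50 codons, a
   length-independent composition statistic.
3. **Copy number** — high-stringency within-genome hits of each gene's
   first 150 bp, binned as single / 2–9 / 10+ copies.
4. **Methylation** — weighted CG, CHG and CHH methylation over the first
   150 bp of each transcript.
5. **Association statistics** — rank-sum contrasts, correlations, binned
   curves and GO-term enrichment.
6. **Synthetic data** — a genome-pair generator with full ground truth, so
   every stage is validated against known labels without any downloads.

The numbered scripts under `analysis/` run these stages as a narrative
workflow; `run_pipeline()` runs them in one call; the test suite holds the
oracle-based validation.

## Block detection

Anchors (homologous gene pairs, normally the product of an all-vs-all
protein-level search) are dots in a gene-order dot plot. Within each
chromosome pair and orientation, a longest-chain dynamic program links
anchors whose gene-rank increments are positive and at most `max_gap` in
both genomes (descending in genome B for antidiagonal blocks). Chains are
extracted best-score-first with anchors removed as they are assigned, so no
anchor lands in two blocks; chains shorter than `min_anchors` are
discarded.

Parameters, with defaults:

* `min_anchors = 7` — the block-size floor; blocks are runs of 7 or more
  gene pairs conserved in order.
* `max_gap = 20` gene ranks — the source analyses delegate chaining to a
  collinearity tool and state only the block-size floor; 20 mirrors common
  defaults of such tools (DAGChainer-family) and is exposed in
  `chain_params()`.
* `collapse_tandems = TRUE`, `tandem_window = 10` — same-chromosome genes
  within 10 ranks sharing an anchor partner are one tandem array,
  represented by the lowest-ordinal member; block membership propagates
  back to every member.

Identity anchors (a gene matched to itself) are dropped before chaining so
self-comparisons measure ancient duplication rather than the trivial
diagonal.

Two properties of the extractor are worth stating precisely. The dynamic
program finds a genuinely longest single chain, so whenever at most one
block can exist (for example, up to 12 anchors under the default floor of
7) extraction is provably optimal, and the test suite verifies equality
with an exhaustive subset-enumeration oracle there. When several blocks
compete for the same anchors, best-first extraction is a heuristic — the
standard one in collinearity tools — and can cover fewer anchors than an
exhaustive packing; at genome scale exhaustive packing is not tractable.

## GC metrics

Genes are filtered before any composition statistic: fewer than 50
complete codons (`too_short`), first codon not ATG (`no_atg`), or any
non-ACGT character (`ambiguous_base`), with that precedence. The ambiguity
filter reads the whole CDS, not only the first 150 bp. Soft-masked
lowercase bases count as their uppercase nucleotide.

`gc3_50()` is the fraction of G/C among the third bases of codons 1–50.
Codon 1 is included: its fixed G shifts every gene identically (a +0.02
floor), so contrasts are unaffected, and values lie on the lattice
0.02–1.00 in steps of 0.02. `gc3_full()` covers all complete codons but
excludes a terminal stop codon, which is constrained (two of three stops
end in A) and would bias the statistic. `positional_gc3_profile()` gives
the per-codon-index mean GC3 used to justify the length-independent
statistic in real data.

## Copy number

The first 150 bp of each CDS is searched against the assembly on both
strands with an ungapped seed-and-extend matcher: an exact 12-nt seed
nominates a diagonal, which counts when identity is at least 90% over at
least 90% of the query. This operationalizes a high-stringency BLASTN
search (E < 1e-30, glossed as >90% identity); exact Karlin–Altschul
E-values are deliberately out of scope. Hits whose spans overlap by half
or more merge into one locus so tandem near-identical repeats are not
double-counted; a precomputed BLAST tabular file can stand in for the
internal matcher with the same locus-merging rule. Counts bin as
`single` (1), `moderate` (2–9) and `repetitive` (10+). A genic query
always finds its own locus, so counts start at 1.

## Weighted methylation

For each gene the 5' window is the first 150 bp of the transcript in
transcription direction (annotated transcript start; for synthetic data
the CDS start). The weighted level per context is the sum of methylated
reads over the sum of total reads across the window's context cytosines on
both strands — pooling reads within a gene, never across genes.
Zero-coverage sites contribute nothing; a gene with no covered context
site is NA for that context. Class summaries (by synteny status or copy
class) are unweighted means of per-gene levels, the convention used for
any table-style comparison in this package. Context strings from allc
files are collapsed to CG/CHG/CHH and trusted as given; when a genome
sequence is available, `assign_context()` recomputes them from the
three-base rule (CG, CHG, CHH with H = A/C/T, read 5'→3' on the
cytosine's own strand) and the generator's outputs are cross-checked this
way in the tests.

## Association statistics

`wilcoxon_rank_sum()` uses midranks; the exact path enumerates the
permutation distribution through a generating-function count over doubled
midranks (ties handled exactly), the approximate path uses the normal
approximation with tie-corrected variance and continuity correction; the
two-sided exact p is `min(1, 2·min(P(W ≤ w), P(W ≥ w)))`. Correlations are
reported as both Pearson and Spearman because the original comparisons do
not name a method; Pearson is treated as primary. GC3-50 histograms use
the natural 2% lattice with no smoothing. Binned methylation curves flag
bins with fewer than 200 covered context sites as not shown. GO enrichment
is a one-sided hypergeometric test per direction for every term with at
least 20 annotated, classified genes per species, significant at raw
p < 0.01 — no multiple-testing correction, matching the convention of the
analyses this package mirrors, with BH-adjusted values emitted as an extra
column for reference.

## The synthetic study system

`generate_genome_pair()` evolves an ancestral gene order (default 2
chromosomes × 300 genes) down two lineages and is the package's study
condition, not a tuning dial. Its design:

* **Two heritable gene classes.** A duplication-prone class (fraction
  0.4) with third-position GC target 0.40 and higher methylation, and a
  duplication-resistant class with target 0.92 and low methylation —
  giving the grass-like bimodal GC3-50 distribution with modes near 40%
  and 92–94%.
* **Events per lineage** (defaults at the 600-gene scale): 4 inversions
  and 2 translocations of 10–30 genes, 20 tandem duplications, 55
  dispersed duplications and 45 losses. Dispersed-duplication sources are
  drawn at 4:1 odds from the prone class, and half the events are
  followed by loss of the original copy — the duplication-then-loss route
  that moves genes and breaks synteny. Class compositions of these draws
  are exact (stratified) rather than binomial, so the configured contrast
  is tight rather than an expectation.
* **Breakpoint separation.** Inversion/translocation regions for both
  lineages are drawn from one ancestral-coordinate pool with every
  breakpoint at least one block length from every other and from
  chromosome ends. Ground-truth blocks — maximal direction-consistent
  runs of surviving ancestral pairs with rank gaps at most `max_gap` —
  are then well defined, and on a rearrangement-only genome pair the
  chaining stage recovers them exactly (anchor-level precision and recall
  of 1.0 in the tests). Without this separation, sub-block fragments
  arise whose block status is genuinely ambiguous.
* **Event-count calibration.** The class GC targets and the 4:1 odds are
  fixed by the motivating observations; the free event densities were
  calibrated once, analytically plus design-time seed sweeps, so that the
  emergent syntenic-minus-non-syntenic GC3-50 difference centers on 0.12
  (the grass range is 10.8–13.0 points) at every genome scale; they are
  not revisited per run.
* **Reads.** Every cytosine in each gene's 5' window gets a per-gene true
  level drawn from class Beta distributions (CG means 0.30/0.10 for
  prone/resistant; CHG 0.10/0.015; CHH 0.02/0.005) and a
  Binomial(30, level) methylated-read count at fixed depth 30.
* **GO annotation.** A third of 30 synthetic terms favor the prone class,
  a third the resistant class, a third neutral, so class-linked
  enrichment is detectable by construction.
* **Determinism.** One seed; every stage derives its own substream, so
  identical configurations are byte-identical and adding a stage never
  perturbs earlier draws. Genes sit on real coordinates (CDS laid out with
  300-bp random spacers), so copy number and methylation operate on an
  actual sequence space. CDS generation avoids stop codons by alphabet
  restriction (after a T in position 1, position 2 avoids A and G) rather
  than rejection sampling.

What the generator does **not** emulate: substitution divergence between
homologs (anchors are given, not re-derived from sequence), introns and
UTRs, polyploidy, CHH islands, the positional 5'→3' GC3 gradient within
genes (the profile function exists for real data, but simulated third
positions are exchangeable), and genome-scale gene counts. Passing tests
therefore demonstrate the correctness of the measurement chain and the
detectability of the configured effect structure — not that real genomes
match these magnitudes.

## Problem sizes

Three configurations ship with the package. `small_sim_config()` (2 × 60
genes) is the quick packaged fixture; a 120-gene chromosome pair can host
only one block-length-separated inversion per lineage, so its event list
is minimal. `sim_config()` (2 × 300) is the default narrative scale used
by the `analysis/` scripts. `large_sim_config()` (2 × 1200, identical
per-gene event densities) is used where a contrast must be resolved at
very small p — with roughly 120 non-syntenic genes at the default scale
the rank-sum p lands near 1e-4–1e-5, while the scaled-up genome yields
p < 1e-15 for the same effect size.

## Numerical conventions and degenerate inputs

Ordinals are dense 0-based ranks per chromosome, assigned by start
coordinate with gene-id tie-break. GFF3 coordinates are 1-based inclusive.
The "first splice variant" is the first mRNA child in file order. Exact
rank-sum enumeration doubles midranks to integers; `auto` mode switches to
the normal approximation when `min(n) > 10` or ties are present. Empty
anchor sets yield empty block sets; a gene set with no genes is an error
for classification; zero-coverage methylation rows are retained but
flagged; chain extraction ties break deterministically toward earlier
(chromosome, ordinal) positions with `+` orientation before `-`.

## Limitations

Block detection is order-based only — no synonymous-substitution
filtering, no syntenic-depth or quota logic, and one-to-many anchors are
resolved only by anchor-disjoint extraction. The copy-number matcher is
ungapped, so indel-diverged copies below 90% ungapped identity are not
counted. GO enrichment takes the annotation as given and ignores the GO
graph. All statistical guarantees verified by the test suite are
statements about the synthetic study system described above.
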
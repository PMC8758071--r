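# syngc

Links gene duplication history to genic GC content and cytosine
methylation in plant genomes. Built for comparative genomicists asking why
grass genes split into a high-GC and a low-GC class: genes that remain
**syntenic** (conserved in gene order against related genomes) have rarely
been duplicated away from their ancestral locus, while dispersed
duplication followed by loss of the original copy produces non-syntenic
genes that are preferential targets of siRNA-directed methylation — and
methylated cytosine erodes toward A:T over evolutionary time.

## What it computes

* **Syntenic blocks** — a longest-chain dynamic program over homolog
  anchor pairs per chromosome pair and orientation, requiring strictly
  monotone gene ranks in both genomes, rank gaps ≤ 20, and ≥ 7 anchor
  pairs per block; tandem arrays collapse to one representative before
  chaining. A gene is *syntenic* when it sits in a block in ≥ 1
  comparison.
* **GC3-50** — the core composition statistic: for a coding sequence with
  codons c₁…cₙ, GC3-50 = (1/50) Σᵢ₌₁⁵⁰ 1[third base of cᵢ ∈ {G,C}],
  after filtering genes with < 50 codons, non-ATG starts or ambiguous
  bases. Length-independent, unlike whole-gene GC3.
* **Copy number** — loci in the assembly matching the first 150 bp of the
  CDS at ≥ 90% identity over ≥ 90% coverage (both strands, overlap-merged),
  binned single / 2–9 / 10+ copies.
* **Weighted methylation** — per gene and context
  m = Σ methylated reads / Σ total reads over the CG, CHG or CHH
  cytosines in the first 150 bp of the transcript.
* **Association statistics** — Wilcoxon rank-sum contrasts (exact
  enumeration for small samples, tie-corrected normal approximation
  otherwise), Pearson/Spearman correlations, 2%-lattice histograms and
  binned methylation curves, and one-sided hypergeometric GO-term
  enrichment per synteny class.
* **Synthetic genomes** — a two-lineage generator with inversions,
  translocations, tandem/dispersed duplications and losses, class-coupled
  GC and methylation, and a full ground-truth record, so the entire
  pipeline is validated against known labels.

## Worked example

The numbered scripts under `analysis/` run the study end to end on a
simulated genome pair (2 chromosomes × 300 genes per lineage, seed 42):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_synteny.R
Rscript analysis/03_gene_metrics.R
Rscript analysis/04_methylation.R
Rscript analysis/05_association.R
```

which prints, step by step:

```
Ground truth: 29 syntenic blocks; 484/602 lineage-A genes truly syntenic
19 blocks chained from 600 anchors; 493/602 A genes syntenic (81.9%)
Gene-level agreement with ground truth: 98.2%
Copy-number classes: moderate=81, single=521
Weighted mCG/mCHG/mCHH: syntenic 17.5/4.9/1.1% vs non-syntenic 19.9/5.6/1.5%
GC3-50 syntenic 72.7% vs non-syntenic 61.7% (diff 11.0 points, W=154096, p=8.70e-04)
Methylation~GC3-50 Pearson r: CG -0.653, CHG -0.522, CHH -0.311 (all negative)
```

Read: block chaining recovers the simulated synteny almost perfectly
(fewer detected than truth blocks because adjacent truth blocks merge
within the gap tolerance — membership, which is what classification uses,
agrees at 98%); syntenic genes run ~11 GC3-50 percentage points above
non-syntenic ones; non-syntenic and higher-copy genes are more methylated
in every context; and methylation correlates negatively with GC3-50 —
the joint pattern the duplication–methylation–GC-erosion model predicts.
Tables land under `results/`, including per-gene metrics
(`gene_metrics_A.tsv`), block lists, class methylation summaries and GO
enrichment.

The same run as one call:

```r
library(syngc)
simulate_fixture(sim_config(seed = 42), "results/sim")
res <- run_pipeline(fixture_pipeline_config("results/sim"), "results/out")
res$stats$comparisons
```

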
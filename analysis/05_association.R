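#!/usr/bin/env Rscript

# Step 5: the association statistics tying duplication history to base
# composition and methylation — rank-sum tests on GC3-50 by class, the
# GC3-50 histograms, methylation~GC3-50 correlations and binned curves,
# and GO-term enrichment by synteny class.

suppressMessages(library(syngc))

tab <- read_gene_table("results/metrics/gene_metrics_A.tsv")
pass <- tab$filter_status == "pass"
dir.create("results/association", showWarnings = FALSE, recursive = TRUE)
tsv <- function(df, f) utils::write.table(df, f, sep = "\t", quote = FALSE,
                                          row.names = FALSE)

# synteny vs GC3-50
x <- tab$gc3_50[pass & tab$syntenic == 1L]
y <- tab$gc3_50[pass & tab$syntenic == 0L]
wt <- wilcoxon_rank_sum(x, y)
cat(sprintf("GC3-50 syntenic %.1f%% vs non-syntenic %.1f%% (diff %.1f points, W=%.0f, p=%.2e)\n",
            100 * mean(x), 100 * mean(y), 100 * (mean(x) - mean(y)),
            wt$statistic, wt$p_value))

# single vs multicopy GC3-50
xs <- tab$gc3_50[pass & tab$copy_class == "single"]
ys <- tab$gc3_50[pass & tab$copy_class != "single"]
ws <- wilcoxon_rank_sum(xs, ys)
cat(sprintf("GC3-50 single-copy %.1f%% vs multicopy %.1f%% (p=%.2e)\n",
            100 * mean(xs), 100 * mean(ys), ws$p_value))
tsv(data.frame(grouping = c("synteny", "copy_number"),
               mean_x = c(mean(x), mean(xs)), mean_y = c(mean(y), mean(ys)),
               n_x = c(length(x), length(xs)), n_y = c(length(y), length(ys)),
               statistic = c(wt$statistic, ws$statistic),
               p_value = c(wt$p_value, ws$p_value)),
    "results/association/rank_sum_tests_A.tsv")

# histograms at the 2% lattice
tsv(gc3_50_distribution(tab$gc3_50[pass],
                        ifelse(tab$syntenic[pass] == 1L, "syntenic",
                               "non_syntenic")),
    "results/association/gc3_distribution_A.tsv")

# methylation ~ GC3-50: correlations and binned curves
meth_cols <- tab[pass, c("gene_id", "mCG", "mCHG", "mCHH")]
meth_like <- data.frame(meth_cols,
                        n_sites_CG = 1L, n_sites_CHG = 1L, n_sites_CHH = 1L,
                        n_reads_CG = 0, n_reads_CHG = 0, n_reads_CHH = 0)
corr <- do.call(rbind, lapply(c("CG", "CHG", "CHH"), function(ctx) {
  v <- tab[[paste0("m", ctx)]][pass]
  ok <- !is.na(v)
  cbind(context = ctx, correlate(tab$gc3_50[pass][ok], v[ok]))
}))
tsv(corr, "results/association/correlations_A.tsv")
r_cg <- corr$r[corr$context == "CG" & corr$method == "pearson"]
cat(sprintf("Methylation~GC3-50 Pearson r: CG %.3f, CHG %.3f, CHH %.3f (all negative)\n",
            r_cg, corr$r[corr$context == "CHG" & corr$method == "pearson"],
            corr$r[corr$context == "CHH" & corr$method == "pearson"]))

curves <- do.call(rbind, lapply(c("CG", "CHG", "CHH"), function(ctx)
  cbind(context = ctx,
        methylation_by_gc3_bins(meth_like,
                                stats::setNames(tab$gc3_50[pass],
                                                tab$gene_id[pass]),
                                context = ctx, min_sites = 0L))))
tsv(curves, "results/association/methylation_by_gc3_bin_A.tsv")

# GO enrichment by synteny class
go_map <- utils::read.delim("results/sim/go_A.tsv")
status <- data.frame(gene_id = tab$gene_id, syntenic = tab$syntenic == 1L)
enr <- go_enrichment(go_map, status, species = "A")
tsv(enr, "results/association/go_enrichment_A.tsv")
cat(sprintf("GO: %d terms tested; %d enriched for syntenic, %d for non-syntenic genes (p<0.01)\n",
            length(unique(enr$go_term)),
            sum(enr$significant & enr$direction == "syntenic"),
            sum(enr$significant & enr$direction == "non_syntenic")))
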
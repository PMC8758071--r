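#' Wilcoxon rank-sum test (two-sided)
#'
#' Rank-sum test with midranks for ties. The exact path enumerates the
#' permutation distribution of the rank sum (via a generating-function
#' count over doubled midranks, so tied samples are handled exactly); the
#' approximate path uses the normal approximation with tie-corrected
#' variance and continuity correction. Mode `auto` uses the exact path
#' when `min(n_x, n_y) <= 10` and there are no ties.
#'
#' The two-sided exact p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y the two samples (non-empty numeric vectors).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `statistic` (rank sum of `x`), `u` (Mann-Whitney U),
#'   `p_value`, and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(m)])
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = min(m, n) <= 10L && !ties)
  if (use_exact) {
    d <- as.integer(round(2 * r))   # doubled midranks are integers
    total <- sum(d)
    # ways[k + 1, s + 1] = number of m-subsets of size k with doubled-rank
    # sum s, built by one pass over the pooled elements
    ways <- matrix(0, nrow = m + 1L, ncol = total + 1L)
    ways[1L, 1L] <- 1
    for (di in d) {
      for (k in rev(seq_len(m))) {
        ways[k + 1L, (di + 1L):(total + 1L)] <-
          ways[k + 1L, (di + 1L):(total + 1L)] +
          ways[k, 1L:(total + 1L - di)]
      }
    }
    dist <- ways[m + 1L, ]
    n_comb <- sum(dist)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1L)]) / n_comb
    p_ge <- sum(dist[(w2 + 1L):(total + 1L)]) / n_comb
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- m * (N + 1) / 2
    tie_tab <- table(pooled)
    sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- w - mu
      z <- z - sign(z) * 0.5           # continuity correction toward the mean
      p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    }
    method <- "normal"
  }
  list(statistic = w, u = w - m * (m + 1) / 2, p_value = p, method = method)
}

#' Correlation between two metrics
#'
#' Computes both Pearson and Spearman correlations (reported side by side)
#' with p-values from the t-distribution transform. Pairs with an NA in
#' either vector are dropped; a zero-variance vector yields NA.
#'
#' @param x,y paired numeric vectors.
#' @param method correlations to compute (default both).
#' @return data.frame with `method`, `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method, several.ok = TRUE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("fewer than 3 complete pairs")
  rows <- lapply(method, function(mth) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(method = mth, r = NA_real_, p_value = NA_real_,
                        n = length(x), stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = mth))
    data.frame(method = mth, r = unname(ct$estimate),
               p_value = ct$p.value, n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram of GC3-50 at the natural 2% lattice
#'
#' GC3-50 values are multiples of 1/50, so percentages fall on the even
#' lattice 0, 2, ..., 100; counts are tallied per group on that lattice
#' with no smoothing.
#'
#' @param gc3 numeric vector of GC3-50 fractions (passing genes only).
#' @param groups character vector of group labels parallel to `gc3`.
#' @return data.frame with `group`, `bin_pct`, `count`; per-group counts
#'   sum to the group's gene total.
#' @export
gc3_50_distribution <- function(gc3, groups = rep("all", length(gc3))) {
  stopifnot(length(groups) == length(gc3))
  ok <- !is.na(gc3) & !is.na(groups)
  gc3 <- gc3[ok]; groups <- groups[ok]
  bin <- as.integer(round(gc3 * 100))
  lattice <- seq(0L, 100L, by = 2L)
  out <- expand.grid(group = unique(groups), bin_pct = lattice,
                     stringsAsFactors = FALSE)
  tab <- table(groups, factor(bin, levels = lattice))
  out$count <- as.integer(tab[cbind(out$group, as.character(out$bin_pct))])
  out[order(out$group, out$bin_pct), , drop = FALSE]
}

#' Mean methylation by GC3-50 bin
#'
#' Bins genes by GC3-50 on the 2% lattice and reports, per bin, the mean
#' per-gene weighted methylation level of one context plus the number of
#' covered context sites pooled over the bin's genes. Bins below
#' `min_sites` context sites are flagged `shown = FALSE` (sparse bins are
#' suppressed when plotting).
#'
#' @param meth per-gene methylation table from [gene_methylation_table].
#' @param gc3 named numeric vector of GC3-50 fractions (names = gene ids),
#'   or a data.frame with `gene_id` and `gc3_50`.
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @param min_sites minimum context-site count for a bin to be shown.
#' @return data.frame with `bin_pct`, `mean_level`, `n_genes`, `n_sites`,
#'   `shown`.
#' @export
methylation_by_gc3_bins <- function(meth, gc3, context = "CG",
                                    min_sites = 200L) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  if (is.data.frame(gc3)) {
    gc3 <- stats::setNames(gc3$gc3_50, gc3$gene_id)
  }
  v <- gc3[meth$gene_id]
  lev <- meth[[paste0("m", context)]]
  sites <- meth[[paste0("n_sites_", context)]]
  ok <- !is.na(v)
  v <- v[ok]; lev <- lev[ok]; sites <- sites[ok]
  bin <- as.integer(round(v * 100))
  rows <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin_pct = b,
               mean_level = if (all(is.na(lev[sel]))) NA_real_
                            else mean(lev[sel], na.rm = TRUE),
               n_genes = sum(sel & !is.na(lev)),
               n_sites = sum(sites[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$shown <- out$n_sites >= min_sites
  out
}

#' GO-term enrichment by synteny class
#'
#' For every GO term annotated to at least `min_genes` genes (among genes
#' holding both an annotation and a synteny status), a one-sided
#' hypergeometric test for over-representation in the syntenic class and,
#' separately, in the non-syntenic class. Significance is called at raw
#' p < `p_cutoff` (no multiple-testing correction, mirroring the raw-P
#' convention of the source analysis); BH-adjusted values are emitted as an
#' extra column for reference.
#'
#' @param go_map data.frame with `gene_id`, `go_term` (one row per
#'   annotation).
#' @param status data.frame with `gene_id`, `syntenic` (logical), as from
#'   [classify_synteny].
#' @param species species tag recorded in the output.
#' @param min_genes per-species term-size floor (default 20).
#' @param p_cutoff raw significance threshold (default 0.01).
#' @return data.frame with one row per term and direction: `species`,
#'   `go_term`, `direction`, `a`, `b`, `c`, `d` (2x2 table:
#'   term-and-syntenic, term-and-non-syntenic, rest-syntenic,
#'   rest-non-syntenic), `p_value`, `p_adj`, `significant`.
#' @export
go_enrichment <- function(go_map, status, species = "sp",
                          min_genes = 20L, p_cutoff = 0.01) {
  if (is.null(go_map) || nrow(go_map) == 0L) stop("empty GO map")
  go_map <- go_map[go_map$gene_id %in% status$gene_id, , drop = FALSE]
  go_map <- go_map[!duplicated(go_map[c("gene_id", "go_term")]), ,
                   drop = FALSE]
  if (nrow(go_map) == 0L) stop("no GO annotation overlaps the classified genes")
  universe <- unique(go_map$gene_id)
  syn <- status$gene_id[status$syntenic]
  K <- sum(universe %in% syn)
  N <- length(universe)
  rows <- list()
  for (term in sort(unique(go_map$go_term))) {
    genes <- unique(go_map$gene_id[go_map$go_term == term])
    k <- length(genes)
    if (k < min_genes) next
    a <- sum(genes %in% syn)
    b <- k - a
    cc <- K - a
    d <- N - K - b
    p_syn <- stats::phyper(a - 1L, K, N - K, k, lower.tail = FALSE)
    p_non <- stats::phyper(a, K, N - K, k, lower.tail = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      species = species, go_term = term,
      direction = c("syntenic", "non_syntenic"),
      a = a, b = b, c = cc, d = d,
      p_value = c(p_syn, p_non), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(species = character(0), go_term = character(0),
                      direction = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (dir in unique(out$direction)) {
    sel <- out$direction == dir
    out$p_adj[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out$significant <- out$p_value < p_cutoff
  rownames(out) <- NULL
  out
}

#' Cross-species enrichment counts
#'
#' Counts, per GO term and direction, in how many species the term is
#' significantly enriched — the basis of "enriched in five or more
#' species"-style summaries.
#'
#' @param enrichments data.frame rbind-ing [go_enrichment] results across
#'   species.
#' @return data.frame with `go_term`, `direction`, `n_species_significant`.
#' @export
cross_species_enrichment <- function(enrichments) {
  if (is.null(enrichments) || nrow(enrichments) == 0L) {
    return(data.frame(go_term = character(0), direction = character(0),
                      n_species_significant = integer(0)))
  }
  out <- stats::aggregate(significant ~ go_term + direction,
                          data = enrichments, FUN = sum)
  names(out)[names(out) == "significant"] <- "n_species_significant"
  out$n_species_significant <- as.integer(out$n_species_significant)
  out <- out[order(-out$n_species_significant, out$go_term, out$direction), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
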
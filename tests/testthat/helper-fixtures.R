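# Shared test helpers: tiny gene sets, toy file writers, and independent
# oracles used by the property tests.

# A gene_set of n genes on one chromosome, gene i at start 10*i.
toy_gene_set <- function(tag, n, chrom = "c1", strand = "+") {
  gene_set(tag, data.frame(
    gene_id = paste0(tag, seq_len(n)), chrom = chrom, strand = strand,
    start = seq_len(n) * 10L, end = seq_len(n) * 10L + 5L,
    stringsAsFactors = FALSE))
}

# Anchors between toy gene sets given ordinal pairs (1-based positions).
toy_anchors <- function(oa, ob, tag_a = "a", tag_b = "b") {
  data.frame(gene_a = paste0(tag_a, oa), gene_b = paste0(tag_b, ob),
             stringsAsFactors = FALSE)
}

write_toy_gff3 <- function(path, genes, mrnas_per_gene = 1L) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, g$start, g$end, g$strand, g$gene_id))
    for (m in seq_len(mrnas_per_gene)) {
      lines <- c(lines,
                 sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.%d;Parent=%s",
                         g$chrom, g$start, g$end, g$strand, g$gene_id, m,
                         g$gene_id))
    }
  }
  writeLines(lines, path)
  path
}

write_toy_fasta <- function(path, seqs) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

random_cds <- function(n_codons, gc3 = 0.5) {
  stopifnot(n_codons >= 1)
  k <- n_codons - 1L
  p1 <- sample(c("A", "C", "G"), k, replace = TRUE)
  p2 <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
  p3 <- ifelse(stats::runif(k) < gc3, sample(c("G", "C"), k, replace = TRUE),
               sample(c("A", "T"), k, replace = TRUE))
  paste0("ATG", paste0(p1, p2, p3, collapse = ""))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent character-position oracle for GC3 statistics.
oracle_gc3 <- function(cds, codons) {
  chars <- strsplit(toupper(cds), "", fixed = TRUE)[[1L]]
  third <- chars[codons * 3L]
  mean(third %in% c("G", "C"))
}

# Exhaustive chain-packing oracle: maximum number of anchors coverable by
# disjoint valid chains (double-monotone, gap-bounded, >= min_anchors) for
# small anchor sets. Independent of the package's dynamic program.
oracle_chain_cover <- function(oa, ob, min_anchors, max_gap) {
  n <- length(oa)
  stopifnot(n <= 14)
  bits <- 2^(0:(n - 1L))
  masks <- 0:(2^n - 1)
  popcount <- vapply(masks, function(m) sum(bitwAnd(m, bits) > 0),
                     numeric(1))
  valid <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    if (popcount[mask + 1] < min_anchors) next
    idx <- which(bitwAnd(mask, bits) > 0)
    op <- order(oa[idx], ob[idx])
    da <- diff(oa[idx][op]); db <- diff(ob[idx][op])
    okp <- all(da > 0 & da <= max_gap) && all(db > 0 & db <= max_gap)
    om <- order(oa[idx], -ob[idx])
    da2 <- diff(oa[idx][om]); db2 <- diff(ob[idx][om])
    okm <- all(da2 > 0 & da2 <= max_gap) && all(db2 < 0 & -db2 <= max_gap)
    if (okp || okm) valid <- c(valid, mask)
  }
  memo <- new.env(hash = TRUE)
  solve <- function(mask) {
    if (mask == 0L) return(0L)
    key <- as.character(mask)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    i_bit <- bits[which(bitwAnd(mask, bits) > 0)[1L]]
    res <- solve(mask - i_bit)
    for (vm in valid) {
      if (bitwAnd(vm, i_bit) > 0 && bitwAnd(vm, mask) == vm) {
        res <- max(res, popcount[vm + 1] + solve(bitwAnd(mask, bitwNot(vm))))
      }
    }
    memo[[key]] <- res
    res
  }
  solve(2L^n - 1L)
}

# Exhaustive rank-sum permutation oracle: two-sided p over all C(N, m)
# group assignments of the pooled values (midranks).
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  combs <- utils::combn(length(pooled), m)
  ws <- apply(combs, 2L, function(idx) sum(r[idx]))
  mu <- mean(ws)
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Anchor-level precision/recall of detected block membership against the
# generator's truth labels (primary pairs inside truth blocks).
recovery_stats <- function(sim, det) {
  ta <- sim$truth$genes_a
  tb <- sim$truth$genes_b
  t_a <- stats::setNames(ta$true_syntenic & ta$origin == "ancestral",
                         ta$gene_id)
  t_b <- stats::setNames(tb$true_syntenic & tb$origin == "ancestral",
                         tb$gene_id)
  truth_pos <- t_a[sim$anchors$gene_a] & t_b[sim$anchors$gene_b]
  det_key <- paste(det$blocks$anchors$gene_a, det$blocks$anchors$gene_b)
  pred_pos <- paste(sim$anchors$gene_a, sim$anchors$gene_b) %in% det_key
  c(precision = sum(pred_pos & truth_pos) / sum(pred_pos),
    recall = sum(pred_pos & truth_pos) / sum(truth_pos))
}
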
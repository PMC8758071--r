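test_that("context assignment follows the three-base rule on both strands", {
  g <- c(chr1 = "ACGTCAGTCATACCGG")
  #       123456789...
  expect_equal(assign_context(g, "chr1", 2L, "+"), "CG")    # CGT
  expect_equal(assign_context(g, "chr1", 5L, "+"), "CHG")   # CAG
  expect_equal(assign_context(g, "chr1", 9L, "+"), "CHH")   # CAT
  expect_equal(assign_context(g, "chr1", 4L, "+"), "none")  # T
  # CCGG: offsets 13-16. C13 -> CHG (C,C,G); C14 -> CG; G15 is a
  # minus-strand C with context CG (revcomp of CCG = CGG)
  expect_equal(assign_context(g, "chr1", 13L, "+"), "CHG")
  expect_equal(assign_context(g, "chr1", 14L, "+"), "CG")
  expect_equal(assign_context(g, "chr1", 15L, "-"), "CG")
  # edges: CG decidable one base from the end, otherwise undefined
  g2 <- c(c2 = "AACG")
  expect_equal(assign_context(g2, "c2", 3L, "+"), "CG")
  g3 <- c(c3 = "AACA")
  expect_true(is.na(assign_context(g3, "c3", 3L, "+")))   # CA? undecidable
  g4 <- c(c4 = "AAAC")
  expect_true(is.na(assign_context(g4, "c4", 4L, "+")))   # C at the end
  expect_equal(assign_context(g4, "c4", 4L, "+"), NA_character_)
})

toy_calls <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1L]], pos = as.integer(r[[2L]]), strand = r[[3L]],
               context = r[[4L]], m_reads = as.integer(r[[5L]]),
               total_reads = as.integer(r[[6L]]), stringsAsFactors = FALSE)))
  df$covered <- df$total_reads > 0L
  df
}

test_that("weighted 5' methylation pools reads within the region", {
  gs <- gene_set("t", data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                                 start = 101L, end = 400L))
  calls <- toy_calls(list("c1", 110, "+", "CG", 2, 5),
                     list("c1", 140, "-", "CG", 0, 5),
                     list("c1", 260, "+", "CG", 9, 9),   # outside 150 bp
                     list("c1", 120, "+", "CHG", 1, 4))
  m <- gene_5prime_methylation("g1", gs, calls)
  expect_equal(m$mCG, 0.2)
  expect_equal(m$mCHG, 0.25)
  expect_true(is.na(m$mCHH))
  expect_equal(m$n_reads_CG, 10)
  expect_equal(m$n_sites_CG, 2L)
})

test_that("minus-strand genes use the transcript-oriented 5' window", {
  gs <- gene_set("t", data.frame(gene_id = "g1", chrom = "c1", strand = "-",
                                 start = 101L, end = 400L))
  calls <- toy_calls(list("c1", 390, "+", "CG", 3, 3),   # inside (end-150, end]
                     list("c1", 120, "+", "CG", 0, 8))   # outside
  m <- gene_5prime_methylation("g1", gs, calls)
  expect_equal(m$mCG, 1)
  expect_equal(m$n_sites_CG, 1L)
})

test_that("per-gene levels match a brute-force tally on random regions", {
  set.seed(61)
  for (rep in 1:200) {
    n_genes <- sample(1:4, 1L)
    starts <- sort(sample(seq(1L, 2000L, by = 200L), n_genes))
    gs <- gene_set("t", data.frame(
      gene_id = paste0("g", seq_len(n_genes)), chrom = "c1",
      strand = sample(c("+", "-"), n_genes, TRUE),
      start = starts, end = starts + sample(150:400, n_genes, TRUE)))
    n_calls <- sample(5:60, 1L)
    tot <- sample(0:20, n_calls, TRUE)
    calls <- data.frame(
      chrom = "c1", pos = sample(1:2500, n_calls),
      strand = sample(c("+", "-"), n_calls, TRUE),
      context = sample(c("CG", "CHG", "CHH"), n_calls, TRUE),
      total_reads = tot, m_reads = vapply(tot, function(t)
        if (t == 0L) 0L else sample(0:t, 1L), integer(1)),
      stringsAsFactors = FALSE)
    calls$covered <- calls$total_reads > 0L
    got <- gene_methylation_table(gs, calls)
    for (i in seq_len(n_genes)) {
      g <- gs$genes[i, ]
      lo <- if (g$strand == "+") g$start else g$end - 149L
      hi <- if (g$strand == "+") g$start + 149L else g$end
      for (ctx in c("CG", "CHG", "CHH")) {
        sel <- calls$pos >= lo & calls$pos <= hi & calls$context == ctx
        expected <- if (sum(calls$total_reads[sel]) == 0) NA_real_
                    else sum(calls$m_reads[sel]) / sum(calls$total_reads[sel])
        expect_equal(got[[paste0("m", ctx)]][i], expected)
      }
    }
  }
})

test_that("merging two calls at one site leaves gene levels unchanged", {
  gs <- gene_set("t", data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                                 start = 1L, end = 200L))
  split_calls <- toy_calls(list("c1", 10, "+", "CG", 2, 5),
                           list("c1", 10, "+", "CG", 1, 7),
                           list("c1", 30, "+", "CG", 0, 4))
  merged_calls <- toy_calls(list("c1", 10, "+", "CG", 3, 12),
                            list("c1", 30, "+", "CG", 0, 4))
  expect_equal(gene_5prime_methylation("g1", gs, split_calls)$mCG,
               gene_5prime_methylation("g1", gs, merged_calls)$mCG)
})

test_that("class aggregation averages per-gene levels, not pooled reads", {
  meth <- data.frame(gene_id = c("g1", "g2", "g3"),
                     mCG = c(0.1, 0.3, 0.9), mCHG = c(NA, NA, 0.2),
                     mCHH = c(NA, NA, NA),
                     n_sites_CG = c(1L, 100L, 2L), n_sites_CHG = 0L,
                     n_sites_CHH = 0L, n_reads_CG = c(10, 1000, 20),
                     n_reads_CHG = 0, n_reads_CHH = 0)
  agg <- aggregate_methylation_by_class(meth, c("x", "x", "y"))
  expect_equal(agg$mean_level[agg$class == "x" & agg$context == "CG"], 0.2)
  expect_true(is.na(agg$mean_level[agg$class == "x" & agg$context == "CHG"]))
  expect_equal(agg$n_genes[agg$class == "y" & agg$context == "CHG"], 1L)
})

test_that("class methylation means are recovered from simulated reads", {
  set.seed(8)
  # 500 genes per class at depth 30, class CG means 0.30 vs 0.10
  n <- 500L
  depth <- 30L
  rec <- vapply(c(prone = 3, resistant = 1), function(a) {
    lv <- stats::rbeta(n, a, 10 - a)
    sites <- 20L
    m <- vapply(lv, function(p) sum(stats::rbinom(sites, depth, p)),
                numeric(1))
    mean(m / (sites * depth))
  }, numeric(1))
  expect_lt(abs(rec["prone"] - 0.30), 0.02)
  expect_lt(abs(rec["resistant"] - 0.10), 0.02)
})
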
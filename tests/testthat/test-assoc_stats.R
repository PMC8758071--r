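test_that("rank-sum test handles the textbook cases", {
  # identical multisets: no evidence of a shift
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # complete separation of 3 vs 3: 2 * 1/20
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)
  expect_equal(r$statistic, 6)
  expect_equal(r$u, 0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact path equals stats::wilcox.test without ties", {
  set.seed(41)
  for (rep in 1:30) {
    x <- stats::rnorm(sample(3:9, 1L))
    y <- stats::rnorm(sample(3:9, 1L)) + stats::runif(1, -1, 1)
    got <- wilcoxon_rank_sum(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$u, unname(ref$statistic))
  }
})

test_that("normal path matches the tie-corrected continuity-corrected
           approximation", {
  set.seed(42)
  for (rep in 1:20) {
    x <- sample(1:6, 30L, replace = TRUE)
    y <- sample(2:7, 25L, replace = TRUE)
    got <- wilcoxon_rank_sum(x, y, mode = "normal")
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact path with ties equals full permutation enumeration", {
  set.seed(43)
  for (rep in 1:40) {
    m <- sample(2:6, 1L)
    n <- sample(2:6, 1L)
    x <- sample(1:4, m, replace = TRUE)   # heavy ties
    y <- sample(2:5, n, replace = TRUE)
    got <- wilcoxon_rank_sum(x, y, mode = "exact")
    expect_equal(got$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("correlations cover linear, constant and formula-checked inputs", {
  x <- 1:10
  r <- correlate(x, 2 * x + 1)
  expect_equal(r$r[r$method == "pearson"], 1)
  expect_true(is.na(correlate(x, rep(5, 10))$r[1L]))
  set.seed(9)
  a <- stats::rnorm(10); b <- stats::rnorm(10)
  got <- correlate(a, b)$r[1L]
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got, manual)
  expect_error(correlate(1:2, 1:2), "fewer than 3")
})

test_that("GC3-50 histograms use the even lattice and conserve totals", {
  d <- gc3_50_distribution(c(0.94), "all")
  expect_equal(d$count[d$bin_pct == 94], 1L)
  set.seed(10)
  gc <- sample(0:50, 200, replace = TRUE) / 50
  grp <- sample(c("syntenic", "non_syntenic"), 200, replace = TRUE)
  d2 <- gc3_50_distribution(gc, grp)
  expect_equal(sum(d2$count[d2$group == "syntenic"]),
               sum(grp == "syntenic"))
  expect_true(all(d2$bin_pct %% 2 == 0))
})

test_that("binned methylation curves flag sparse bins and match tallies", {
  meth <- data.frame(
    gene_id = paste0("g", 1:5),
    mCG = c(0.2, 0.4, 0.1, NA, 0.6), mCHG = 0.1, mCHH = 0.1,
    n_sites_CG = c(150L, 120L, 90L, 10L, 500L),
    n_sites_CHG = 0L, n_sites_CHH = 0L,
    n_reads_CG = 1, n_reads_CHG = 1, n_reads_CHH = 1)
  gc3 <- stats::setNames(c(0.40, 0.40, 0.42, 0.42, 0.94), meth$gene_id)
  bc <- methylation_by_gc3_bins(meth, gc3, context = "CG")
  b40 <- bc[bc$bin_pct == 40, ]
  expect_equal(b40$mean_level, 0.3)
  expect_equal(b40$n_sites, 270L)
  expect_true(b40$shown)
  b42 <- bc[bc$bin_pct == 42, ]
  expect_equal(b42$mean_level, 0.1)   # NA gene excluded from the mean
  expect_false(b42$shown)             # 100 < 200 context sites
  b94 <- bc[bc$bin_pct == 94, ]
  expect_equal(b94$n_genes, 1L)
  expect_equal(b94$mean_level, 0.6)
})

test_that("GO enrichment applies the term-size floor and exact tails", {
  status <- data.frame(gene_id = sprintf("g%03d", 1:200),
                       syntenic = rep(c(TRUE, FALSE), each = 100))
  # term T1: 15 syntenic + 5 non-syntenic (passes the floor of 20);
  # term T2: 19 genes (excluded); term T3: perfectly balanced
  go <- rbind(
    data.frame(gene_id = c(sprintf("g%03d", 1:15), sprintf("g%03d", 101:105)),
               go_term = "T1"),
    data.frame(gene_id = c(sprintf("g%03d", 30:39), sprintf("g%03d", 130:138)),
               go_term = "T2"),
    data.frame(gene_id = c(sprintf("g%03d", 50:69), sprintf("g%03d", 150:169)),
               go_term = "T3"))
  enr <- go_enrichment(go, status, species = "sp")
  expect_false("T2" %in% enr$go_term)
  t3 <- enr[enr$go_term == "T3", ]
  expect_true(all(!t3$significant))
  # exact tail: universe is every annotated + classified gene
  t1 <- enr[enr$go_term == "T1" & enr$direction == "syntenic", ]
  uni <- unique(go$gene_id)
  K <- sum(uni %in% status$gene_id[status$syntenic])
  p_manual <- sum(stats::dhyper(t1$a:(t1$a + t1$b), K, length(uni) - K,
                                t1$a + t1$b))
  expect_equal(t1$p_value, p_manual, tolerance = 1e-12)
  expect_error(go_enrichment(go[0, ], status), "empty")
})

test_that("hypergeometric tail probabilities sum to one", {
  K <- 40L; N <- 100L; k <- 25L
  probs <- stats::dhyper(0:k, K, N - K, k)
  expect_equal(sum(probs), 1)
})

test_that("cross-species counts accumulate significant directions", {
  enr <- data.frame(
    species = rep(c("s1", "s2", "s3"), each = 2),
    go_term = "T", direction = rep(c("syntenic", "non_syntenic"), 3),
    significant = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  cs <- cross_species_enrichment(enr)
  expect_equal(cs$n_species_significant[cs$direction == "syntenic"], 2L)
  expect_equal(cs$n_species_significant[cs$direction == "non_syntenic"], 1L)
})
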
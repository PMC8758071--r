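gs14a <- toy_gene_set("a", 40)
gs14b <- toy_gene_set("b", 40)

test_that("a perfect diagonal chains into a single forward block", {
  anc <- toy_anchors(1:10, 1:10)
  blk <- chain_anchors(anc, gs14a, gs14b)
  expect_equal(nrow(blk$blocks), 1L)
  expect_equal(blk$blocks$n_anchors, 10L)
  expect_equal(blk$blocks$orientation, "+")
})

test_that("blocks below the 7-gene floor are discarded", {
  anc <- toy_anchors(1:6, 1:6)
  blk <- chain_anchors(anc, gs14a, gs14b)
  expect_equal(nrow(blk$blocks), 0L)
})

test_that("a descending run is reported as an antidiagonal block", {
  anc <- toy_anchors(1:7, 7:1)
  blk <- chain_anchors(anc, gs14a, gs14b)
  expect_equal(nrow(blk$blocks), 1L)
  expect_equal(blk$blocks$orientation, "-")
})

test_that("internal gaps chain within max_gap and split beyond it", {
  # 8 collinear anchors with an internal rank gap of 5
  oa <- c(1:4, 10:13)
  anc <- toy_anchors(oa, oa)
  blk <- chain_anchors(anc, gs14a, gs14b)
  expect_equal(blk$blocks$n_anchors, 8L)
  # a gap of 25 exceeds max_gap 20: two fragments of 4, both below 7
  gs_big_a <- toy_gene_set("a", 60)
  gs_big_b <- toy_gene_set("b", 60)
  oa2 <- c(1:4, 30:33)
  blk2 <- chain_anchors(toy_anchors(oa2, oa2), gs_big_a, gs_big_b)
  expect_equal(nrow(blk2$blocks), 0L)
})

test_that("identity anchors of a self-comparison are excluded", {
  anc <- data.frame(gene_a = paste0("a", 1:10), gene_b = paste0("a", 1:10))
  blk <- chain_anchors(anc, gs14a, gs14a)
  expect_equal(nrow(blk$blocks), 0L)
})

test_that("tandem arrays collapse to their lowest-ordinal member", {
  # a3, a4, a5 all hit b3; a diagonal run elsewhere keeps the block alive
  anc <- rbind(toy_anchors(c(3, 4, 5), c(3, 3, 3)),
               toy_anchors(c(6:12), c(4:10)))
  col <- collapse_tandem_arrays(anc, gs14a, gs14b)
  expect_equal(sum(col$anchors$gene_b == "b3"), 1L)
  expect_equal(col$anchors$gene_a[col$anchors$gene_b == "b3"], "a3")
  expect_equal(unname(col$rep_a[c("a3", "a4", "a5")]), rep("a3", 3L))
  # status propagates to every collapsed member
  det <- detect_synteny(anc, gs14a, gs14b)
  expect_true(all(c("a3", "a4", "a5") %in% det$members_a))

  off <- collapse_tandem_arrays(anc, gs14a, gs14b,
                                chain_params(collapse_tandems = FALSE))
  expect_equal(nrow(off$anchors), nrow(anc))
})

test_that("synteny classification unions comparisons", {
  gs <- toy_gene_set("a", 10)
  memb <- list(vsB = c("a1", "a2", "a3"), vsC = c("a3", "a4"))
  st <- classify_synteny(gs, memb)
  expect_equal(sum(st$syntenic), 4L)
  expect_equal(st$n_support[st$gene_id == "a3"], 2L)
  expect_equal(st$supporting[st$gene_id == "a4"], "vsC")
  expect_false(st$syntenic[st$gene_id == "a9"])
  expect_error(classify_synteny(gene_set("x", data.frame(
    gene_id = character(0), chrom = character(0), strand = character(0),
    start = integer(0), end = integer(0))), memb), "empty")
})

test_that("summary matrix union respects set algebra", {
  expect_equal(synteny_summary_matrix(list(one = c("a", "b", "c")))$n_syntenic,
               c(3L, 3L))
  m <- synteny_summary_matrix(list(x = c("a", "b", "c"), y = c("d", "e", "f", "g")))
  expect_equal(m$n_syntenic[m$comparison == "union"], 7L)
  m2 <- synteny_summary_matrix(list(x = letters[1:5], y = letters[1:9]))
  expect_equal(m2$n_syntenic[m2$comparison == "union"], 9L)
})

test_that("chained blocks always satisfy the collinearity contract", {
  set.seed(11)
  params <- chain_params(min_anchors = 4L, max_gap = 6L)
  gs_a <- toy_gene_set("a", 30)
  gs_b <- toy_gene_set("b", 30)
  for (rep in 1:40) {
    n <- sample(10:40, 1L)
    anc <- unique(toy_anchors(sample(1:30, n, TRUE), sample(1:30, n, TRUE)))
    blk <- chain_anchors(anc, gs_a, gs_b, params)
    expect_silent(validate_blocks(blk, params))
  }
})

test_that("longest-chain extraction matches the exhaustive oracle when a
           single block is feasible", {
  set.seed(23)
  params <- chain_params()  # min 7, gap 20
  gs_a <- toy_gene_set("a", 40)
  gs_b <- toy_gene_set("b", 40)
  for (rep in 1:40) {
    n <- sample(4:12, 1L)
    pts <- unique(data.frame(oa = sample(1:40, n, TRUE),
                             ob = sample(1:40, n, TRUE)))
    # bias half the cases toward near-diagonal structure so chains exist
    if (rep %% 2 == 0) {
      m <- sample(7:12, 1L)
      s <- sort(sample(3:30, m))
      pts <- unique(rbind(pts, data.frame(oa = s, ob = s + sample(-2:2, 1L))))
      pts <- pts[seq_len(min(nrow(pts), 12L)), ]
    }
    blk <- chain_anchors(toy_anchors(pts$oa, pts$ob), gs_a, gs_b, params)
    expect_equal(nrow(blk$anchors),
                 oracle_chain_cover(pts$oa, pts$ob, params$min_anchors,
                                    params$max_gap))
  }
})

test_that("raising min_anchors never increases the syntenic gene count", {
  set.seed(31)
  sim <- generate_genome_pair(small_sim_config(seed = 5))
  counts <- vapply(c(3L, 5L, 7L, 9L, 12L), function(k) {
    det <- detect_synteny(sim$anchors, sim$gene_set_a, sim$gene_set_b,
                          chain_params(min_anchors = k))
    length(det$members_a)
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})
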
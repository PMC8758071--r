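test_that("a no-event simulation reproduces the ancestor in both lineages", {
  cfg <- sim_config(seed = 3, genes_per_chromosome = 20L,
                    n_inversions = 0L, n_translocations = 0L,
                    n_dispersed_duplications = 0L,
                    n_tandem_duplications = 0L, n_losses = 0L)
  sim <- generate_genome_pair(cfg)
  expect_equal(nrow(sim$gene_set_a$genes), 40L)
  expect_equal(sim$truth$genes_a$anc_id[order(sim$gene_set_a$genes$chrom,
                                              sim$gene_set_a$genes$ordinal)],
               sim$truth$genes_b$anc_id[order(sim$gene_set_b$genes$chrom,
                                              sim$gene_set_b$genes$ordinal)])
  # one truth block per chromosome, everything truly syntenic
  expect_equal(nrow(sim$truth$blocks), 2L)
  expect_true(all(sim$truth$genes_a$true_syntenic))
  expect_true(all(sim$truth$genes_b$true_syntenic))
})

test_that("a dispersed duplication with forced loss breaks synteny", {
  cfg <- sim_config(seed = 11, genes_per_chromosome = 30L,
                    n_inversions = 0L, n_translocations = 0L,
                    n_dispersed_duplications = 1L,
                    n_tandem_duplications = 0L, n_losses = 0L,
                    loss_after_duplication = 1)
  sim <- generate_genome_pair(cfg)
  moved_a <- sim$truth$genes_a[sim$truth$genes_a$origin == "dispersed", ]
  expect_equal(nrow(moved_a), 1L)
  expect_false(moved_a$true_syntenic)
  # the ancestral copy is gone from lineage A
  expect_false(any(sim$truth$genes_a$origin == "ancestral" &
                   sim$truth$genes_a$anc_id == moved_a$anc_id))
})

test_that("identical seeds reproduce bit-identical fixtures", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  d3 <- file.path(tempdir(), "fx3")
  simulate_fixture(small_sim_config(seed = 9), d1)
  simulate_fixture(small_sim_config(seed = 9), d2)
  simulate_fixture(small_sim_config(seed = 10), d3)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genes_A.gff3"))),
                         unname(tools::md5sum(file.path(d3, "genes_A.gff3")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("generated CDS honor class targets and never contain stops", {
  cfg <- sim_config()
  set.seed(2)
  cds_hi <- generate_cds("resistant", sim_config(gc3_target_high = 1), n = 5L)
  expect_true(all(gc3_50(cds_hi) == 1))
  cds_lo <- generate_cds("prone", sim_config(gc3_target_low = 0), n = 5L)
  expect_true(all(gc3_50(cds_lo) == 0.02))
  cds <- generate_cds("prone", cfg, n = 50L)
  expect_true(all(filter_cds(cds) == "pass"))
  for (s in cds) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
  # binomial expectation at the default high target
  set.seed(4)
  n <- 2000L
  m <- mean(gc3_50(generate_cds("resistant", cfg, n = n)))
  expected <- 0.92 * 49 / 50 + 1 / 50
  expect_lt(abs(m - expected), 3 * sqrt(expected * (1 - expected) / 50 / n))
})

test_that("bisulfite simulation produces consistent degenerate cases", {
  cfg <- small_sim_config(seed = 6,
                          meth_beta = list(
                            prone = list(CG = c(1e6, 1), CHG = c(1e6, 1),
                                         CHH = c(1e6, 1)),
                            resistant = list(CG = c(1e6, 1), CHG = c(1e6, 1),
                                             CHH = c(1e6, 1))))
  sim <- generate_genome_pair(cfg)
  bs <- simulate_bisulfite_calls(sim$gene_set_a, sim$genome_a,
                                 sim$truth$genes_a, cfg)
  bs$calls$context <- collapse_context(bs$calls$context3)
  bs$calls$covered <- bs$calls$total_reads > 0
  mt <- gene_methylation_table(sim$gene_set_a, bs$calls)
  expect_true(all(mt$mCG[mt$n_sites_CG > 0] == 1))

  cfg0 <- small_sim_config(seed = 6, read_depth = 0L)
  bs0 <- simulate_bisulfite_calls(sim$gene_set_a, sim$genome_a,
                                  sim$truth$genes_a, cfg0)
  bs0$calls$context <- collapse_context(bs0$calls$context3)
  bs0$calls$covered <- bs0$calls$total_reads > 0
  mt0 <- gene_methylation_table(sim$gene_set_a, bs0$calls)
  expect_true(all(is.na(mt0$mCG)))
})

test_that("simulated contexts match the genome sequence", {
  cfg <- small_sim_config(seed = 14)
  sim <- generate_genome_pair(cfg)
  bs <- simulate_bisulfite_calls(sim$gene_set_a, sim$genome_a,
                                 sim$truth$genes_a, cfg)
  calls <- bs$calls[sample.int(nrow(bs$calls), 300L), ]
  recomputed <- assign_context(sim$genome_a, calls$chrom, calls$pos,
                               calls$strand)
  expect_equal(collapse_context(calls$context3), recomputed)
})

test_that("simulated class coupling reproduces the expected joint pattern", {
  cfg <- sim_config(seed = 12)
  sim <- generate_genome_pair(cfg)
  truth <- sim$truth$genes_a
  gc <- gene_gc_table(sim$gene_set_a)
  # non-syntenic genes have lower GC3-50 on average
  expect_lt(mean(gc$gc3_50[!truth$true_syntenic], na.rm = TRUE),
            mean(gc$gc3_50[truth$true_syntenic], na.rm = TRUE))
  # and higher methylation in every context
  bs <- simulate_bisulfite_calls(sim$gene_set_a, sim$genome_a, truth, cfg)
  bs$calls$context <- collapse_context(bs$calls$context3)
  bs$calls$covered <- bs$calls$total_reads > 0
  mt <- gene_methylation_table(sim$gene_set_a, bs$calls)
  for (ctx in c("mCG", "mCHG", "mCHH")) {
    expect_gt(mean(mt[[ctx]][!truth$true_syntenic], na.rm = TRUE),
              mean(mt[[ctx]][truth$true_syntenic], na.rm = TRUE))
  }
})

test_that("truth blocks satisfy the collinearity contract", {
  sim <- generate_genome_pair(sim_config(seed = 20))
  blk <- sim$truth$blocks
  expect_true(all(blk$n_pairs >= 7L))
  expect_true(all(blk$a_end >= blk$a_start))
  # chaining at truth-matched parameters recovers the truth exactly on a
  # rearrangement-only genome pair
  cfg <- sim_config(seed = 20, n_dispersed_duplications = 0L,
                    n_tandem_duplications = 0L, n_losses = 0L)
  sim2 <- generate_genome_pair(cfg)
  det <- detect_synteny(sim2$anchors, sim2$gene_set_a, sim2$gene_set_b)
  st <- recovery_stats(sim2, det)
  expect_equal(unname(st["precision"]), 1)
  expect_equal(unname(st["recall"]), 1)
})
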
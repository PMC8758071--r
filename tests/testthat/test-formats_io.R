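test_that("gene models load from GFF3 with per-chromosome ordinals", {
  genes <- data.frame(
    gene_id = c("g2", "g1", "g3"), chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"), start = c(500L, 100L, 50L),
    end = c(600L, 200L, 80L), stringsAsFactors = FALSE)
  gff <- write_toy_gff3(tempfile(fileext = ".gff3"), genes)
  fa <- write_toy_fasta(tempfile(fileext = ".fa"),
                        c(g1.1 = "ATGAAA", g2.1 = "ATGCCC", g3.1 = "ATGGGG"))
  gs <- read_gene_models(gff, fa, "toy")
  expect_s3_class(gs, "gene_set")
  expect_equal(nrow(gs$genes), 3L)
  # ordinals follow start coordinate within each chromosome
  expect_equal(gs$genes$ordinal[gs$genes$gene_id == "g1"], 0L)
  expect_equal(gs$genes$ordinal[gs$genes$gene_id == "g2"], 1L)
  expect_equal(gs$genes$ordinal[gs$genes$gene_id == "g3"], 0L)
  expect_equal(unname(gs$cds["g2"]), "ATGCCC")
})

test_that("empty GFF3 yields an empty gene set", {
  gff <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff)
  gs <- read_gene_models(gff, NULL, "empty")
  expect_equal(nrow(gs$genes), 0L)
})

test_that("first mRNA by file order supplies the CDS; unmatched CDS warns", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 1L, end = 90L, stringsAsFactors = FALSE)
  gff <- write_toy_gff3(tempfile(fileext = ".gff3"), genes,
                        mrnas_per_gene = 2L)
  fa <- write_toy_fasta(tempfile(fileext = ".fa"),
                        c(g1.1 = "ATGAAACCC", g1.2 = "ATGTTT"))
  gs <- read_gene_models(gff, fa, "toy")
  expect_equal(unname(gs$cds["g1"]), "ATGAAACCC")

  fa2 <- write_toy_fasta(tempfile(fileext = ".fa"), c(other = "ATG"))
  expect_warning(gs2 <- read_gene_models(gff, fa2, "toy"),
                 "without matching CDS")
  expect_equal(nrow(gs2$genes), 1L)  # gene retained, no sequence
  expect_false("g1" %in% names(gs2$cds))
})

test_that("malformed GFF3 line is reported with its line number", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t1\t10\t.\t+\t.\tID=g1",
               "chr1\ttoy\tgene\t20"), gff)
  expect_error(read_gene_models(gff, NULL, "toy"), "line 3")
})

test_that("anchor pairs resolve, dedupe and report drops", {
  gs_a <- toy_gene_set("a", 5)
  gs_b <- toy_gene_set("b", 5)
  f <- tempfile()
  writeLines(c("a1\tb1\t90", "a2\tb2\t80", "a3\tb3\t70"), f)
  expect_equal(nrow(read_anchor_pairs(f, gs_a, gs_b)), 3L)

  writeLines(c("a1\tb1", "a2\tb2", "aX\tb3"), f)
  expect_message(anc <- read_anchor_pairs(f, gs_a, gs_b), "dropped 1")
  expect_equal(nrow(anc), 2L)

  writeLines(c("a1\tb1", "a1\tb1", "a2\tb2"), f)
  expect_equal(nrow(read_anchor_pairs(f, gs_a, gs_b)), 2L)

  writeLines("aX\tbX", f)
  expect_error(read_anchor_pairs(f, gs_a, gs_b), "no resolvable")
})

test_that("methylation calls collapse contexts and validate counts", {
  f <- tempfile()
  writeLines(c("chr1\t10\t+\tCGT\t3\t4",
               "chr1\t11\t-\tCAG\t0\t7",
               "chr1\t12\t+\tCCC\t1\t2",
               "chr1\t13\t+\tCG\t2\t9",
               "chr1\t14\t+\tCAT\t0\t0"), f)
  calls <- read_methylation_calls(f)
  expect_equal(calls$context, c("CG", "CHG", "CHH", "CG", "CHH"))
  expect_equal(calls$covered, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  writeLines("chr1\t10\t+\tCGT\t5\t4", f)
  expect_error(read_methylation_calls(f), "row 1")
})

test_that("gene table round-trips bit-exactly", {
  set.seed(7)
  n <- 1000L
  lattice4 <- function(n) round(stats::runif(n), 4)
  rec <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    species = sample(c("A", "B"), n, TRUE),
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    ordinal = sample.int(5000L, n),
    syntenic = sample(0:1, n, TRUE),
    gc3_50 = ifelse(stats::runif(n) < 0.1, NA, sample(0:50, n, TRUE) / 50),
    gc3_full = lattice4(n),
    copy_class = sample(c("single", "moderate", "repetitive"), n, TRUE),
    mCG = lattice4(n), mCHG = lattice4(n),
    mCHH = ifelse(stats::runif(n) < 0.2, NA, lattice4(n)),
    filter_status = sample(c("pass", "too_short", "no_atg"), n, TRUE),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_gene_table(rec, f, header_comment = "test run")
  back <- read_gene_table(f)
  expect_equal(back, rec)
})

test_that("a gene failing CDS filters is written with NA metrics", {
  rec <- data.frame(gene_id = "g1", species = "A", chrom = "c", ordinal = 0L,
                    syntenic = 0L, gc3_50 = NA_real_, gc3_full = NA_real_,
                    copy_class = NA_character_, mCG = NA_real_,
                    mCHG = NA_real_, mCHH = NA_real_,
                    filter_status = "too_short", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_gene_table(rec, f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_match(lines[2L], "NA\tNA\tNA\tNA\tNA\tNA\ttoo_short")
})
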
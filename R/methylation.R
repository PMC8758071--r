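#' Assign the methylation context of a cytosine
#'
#' Reads three bases 5'->3' on the cytosine's own strand (reverse
#' complement for `-`): `CG` when base 2 is G; `CHG` when base 2 is H
#' (A/C/T) and base 3 is G; `CHH` when bases 2 and 3 are both H. Positions
#' too close to a sequence end resolve with the available bases: CG is
#' decidable one base from the end, anything else is undefined (NA).
#' Positions whose strand-adjusted base is not a cytosine return `"none"`.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom,pos,strand parallel vectors locating the cytosines
#'   (1-based positions; strand `+` or `-`).
#' @return character vector in `{CG, CHG, CHH, none}` or NA (undecidable).
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  if (inherits(genome, "prepared_genome")) {
    genome <- as.character(genome$seqs)
  }
  genome <- toupper(genome)
  lens <- nchar(genome)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n)
  seqs <- genome[chrom]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  base_at <- function(p) {
    ok <- p >= 1L & p <= lens[chrom]
    out <- rep(NA_character_, n)
    out[ok] <- substring(seqs[ok], p[ok], p[ok])
    out
  }
  plus <- strand == "+"
  step <- ifelse(plus, 1L, -1L)
  b1 <- base_at(pos)
  b2 <- base_at(pos + step)
  b3 <- base_at(pos + 2L * step)
  b1[!plus] <- unname(comp[b1[!plus]])
  b2[!plus] <- unname(comp[b2[!plus]])
  b3[!plus] <- unname(comp[b3[!plus]])
  out <- rep(NA_character_, n)
  out[!is.na(b1) & b1 != "C"] <- "none"
  isc <- !is.na(b1) & b1 == "C"
  out[isc & !is.na(b2) & b2 == "G"] <- "CG"
  h2 <- isc & !is.na(b2) & b2 %in% c("A", "C", "T")
  out[h2 & !is.na(b3) & b3 == "G"] <- "CHG"
  out[h2 & !is.na(b3) & b3 %in% c("A", "C", "T")] <- "CHH"
  out
}

# Strand-aware 5' region of each gene: the first region_len bases of the
# transcript in transcription direction.
gene_5prime_regions <- function(genes, region_len) {
  plus <- genes$strand == "+"
  low <- genes$end - region_len + 1L
  if (any(!plus & low < 1L)) {
    warning("5' region truncated at chromosome start for ",
            sum(!plus & low < 1L), " gene(s)")
  }
  rs <- ifelse(plus, genes$start, pmax(low, 1L))
  re <- ifelse(plus, genes$start + region_len - 1L, genes$end)
  data.frame(chrom = genes$chrom, start = as.integer(rs),
             end = as.integer(re), stringsAsFactors = FALSE)
}

#' Weighted 5'-end methylation per gene
#'
#' For every gene, the weighted methylation level over the first
#' `region_len` bases of the transcript (strand-aware: `[start, start+150)`
#' on `+`, `(end-150, end]` on `-`), separately for CG, CHG and CHH
#' contexts: sum of methylated reads divided by sum of total reads over the
#' context cytosines inside the region, both strands included. Sites with
#' zero coverage contribute nothing; the level is NA when the region holds
#' no covered context site.
#'
#' @param geneset a [gene_set] with genomic coordinates and strands.
#' @param calls methylation calls from [read_methylation_calls].
#' @param region_len length of the 5' window (default 150 bp).
#' @return data.frame with `gene_id`, `mCG`, `mCHG`, `mCHH`, and per
#'   context `n_sites_*` (covered sites) and `n_reads_*` (total reads).
#' @export
gene_methylation_table <- function(geneset, calls, region_len = 150L) {
  genes <- geneset$genes
  regions <- gene_5prime_regions(genes, region_len)
  contexts <- c("CG", "CHG", "CHH")
  ng <- nrow(genes)
  m_sum <- matrix(0, ng, 3L, dimnames = list(NULL, contexts))
  t_sum <- matrix(0, ng, 3L, dimnames = list(NULL, contexts))
  s_cnt <- matrix(0L, ng, 3L, dimnames = list(NULL, contexts))
  for (chr in unique(regions$chrom)) {
    gi <- which(regions$chrom == chr)
    ci <- which(calls$chrom == chr)
    if (length(ci) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(calls$pos[ci], width = 1L),
      IRanges::IRanges(regions$start[gi], regions$end[gi]))
    if (length(ov) == 0L) next
    call_row <- ci[S4Vectors::from(ov)]
    gene_row <- gi[S4Vectors::to(ov)]
    for (ctx in contexts) {
      sel <- calls$context[call_row] == ctx
      if (!any(sel)) next
      g <- gene_row[sel]
      cr <- call_row[sel]
      ms <- rowsum(as.numeric(calls$m_reads[cr]), g)
      ts <- rowsum(as.numeric(calls$total_reads[cr]), g)
      cs <- rowsum(as.integer(calls$total_reads[cr] > 0L), g)
      idx <- as.integer(rownames(ms))
      m_sum[idx, ctx] <- m_sum[idx, ctx] + ms[, 1L]
      t_sum[idx, ctx] <- t_sum[idx, ctx] + ts[, 1L]
      s_cnt[idx, ctx] <- s_cnt[idx, ctx] + cs[, 1L]
    }
  }
  level <- m_sum / t_sum
  level[t_sum == 0] <- NA_real_
  data.frame(
    gene_id = genes$gene_id,
    mCG = level[, "CG"], mCHG = level[, "CHG"], mCHH = level[, "CHH"],
    n_sites_CG = s_cnt[, "CG"], n_sites_CHG = s_cnt[, "CHG"],
    n_sites_CHH = s_cnt[, "CHH"],
    n_reads_CG = t_sum[, "CG"], n_reads_CHG = t_sum[, "CHG"],
    n_reads_CHH = t_sum[, "CHH"],
    stringsAsFactors = FALSE
  )
}

#' Weighted 5'-end methylation of a single gene
#'
#' @param gene_id the gene to profile.
#' @inheritParams gene_methylation_table
#' @return one-row data.frame as in [gene_methylation_table].
#' @export
gene_5prime_methylation <- function(gene_id, geneset, calls,
                                    region_len = 150L) {
  idx <- match(gene_id, geneset$genes$gene_id)
  if (is.na(idx)) stop("unknown gene_id: ", gene_id)
  sub <- geneset
  sub$genes <- geneset$genes[idx, , drop = FALSE]
  gene_methylation_table(sub, calls, region_len)
}

#' Average methylation by gene class
#'
#' Class-level summaries in the style of per-class methylation tables: the
#' unweighted mean across genes of per-gene weighted levels (reads are
#' pooled within a gene's region, but not across genes), per context, with
#' NA genes excluded per context.
#'
#' @param meth per-gene methylation table from [gene_methylation_table].
#' @param labels character vector of class labels parallel to `meth` rows
#'   (e.g. syntenic/non-syntenic, or copy classes). NA labels are dropped.
#' @return data.frame with `class`, `context`, `mean_level`, `n_genes`.
#' @export
aggregate_methylation_by_class <- function(meth, labels) {
  stopifnot(length(labels) == nrow(meth))
  keep <- !is.na(labels)
  if (!all(keep)) {
    meth <- meth[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  classes <- unique(labels)
  rows <- list()
  for (cl in classes) {
    sel <- labels == cl
    if (!any(sel)) {
      warning("class with 0 genes omitted: ", cl)
      next
    }
    for (ctx in c("CG", "CHG", "CHH")) {
      v <- meth[[paste0("m", ctx)]][sel]
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, context = ctx,
        mean_level = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
        n_genes = sum(!is.na(v)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
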
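#' CDS quality filters
#'
#' Genes shorter than 50 codons, genes containing ambiguous bases and genes
#' whose first codon is not ATG are excluded from GC analysis. Precedence
#' when several conditions hold: `too_short` over `no_atg` over
#' `ambiguous_base`. Lowercase (soft-masked) bases are treated as their
#' uppercase nucleotide.
#'
#' @param cds character vector of coding sequences.
#' @return character vector of filter statuses in
#'   `{pass, too_short, no_atg, ambiguous_base}`.
#' @export
filter_cds <- function(cds) {
  if (length(cds) == 0L) return(character(0))
  if (any(is.na(cds) | !nzchar(cds))) stop("empty CDS string")
  cds <- toupper(cds)
  n_codons <- nchar(cds) %/% 3L
  status <- rep("pass", length(cds))
  ambiguous <- grepl("[^ACGT]", cds)
  status[ambiguous] <- "ambiguous_base"
  status[substr(cds, 1L, 3L) != "ATG"] <- "no_atg"
  status[n_codons < 50L] <- "too_short"
  status
}

# G/C indicator over selected third-codon positions of one uppercase CDS.
third_positions_gc <- function(cds, codons) {
  pos <- codons * 3L
  chars <- substring(cds, pos, pos)
  chars %in% c("G", "C")
}

#' GC content at the third position of the first 50 codons (GC3-50)
#'
#' The fraction of G or C among the third bases of codons 1-50 of a coding
#' sequence. Codon 1 (the ATG start, which contributes its fixed G) is
#' included, so the value lies on the lattice 0.02, 0.04, ..., 1.00.
#' GC3-50 is a length-independent variant of GC3: plant genic GC3 declines
#' with distance from the start codon, so whole-gene GC3 is confounded with
#' gene length.
#'
#' @param cds character vector of coding sequences that pass [filter_cds].
#' @return numeric vector of GC3-50 fractions in `[0, 1]`.
#' @export
gc3_50 <- function(cds) {
  if (length(cds) == 0L) return(numeric(0))
  status <- filter_cds(cds)
  if (any(status != "pass")) {
    stop("gc3_50 called on a CDS failing filters (",
         status[status != "pass"][1L], ")")
  }
  cds <- toupper(cds)
  vapply(cds, function(s) sum(third_positions_gc(s, 1:50)) / 50,
         numeric(1), USE.NAMES = FALSE)
}

#' Whole-gene GC3
#'
#' G/C fraction over the third positions of all complete codons of a coding
#' sequence, excluding a terminal stop codon (TAA/TAG/TGA) when present —
#' stop codons are constrained (two of three end in A) and would bias the
#' statistic.
#'
#' @inheritParams gc3_50
#' @return numeric vector of GC3 fractions in `[0, 1]`.
#' @export
gc3_full <- function(cds) {
  if (length(cds) == 0L) return(numeric(0))
  status <- filter_cds(cds)
  if (any(status != "pass")) {
    stop("gc3_full called on a CDS failing filters (",
         status[status != "pass"][1L], ")")
  }
  cds <- toupper(cds)
  vapply(cds, function(s) {
    n <- nchar(s) %/% 3L
    last <- substring(s, 3L * n - 2L, 3L * n)
    if (last %in% c("TAA", "TAG", "TGA")) n <- n - 1L
    sum(third_positions_gc(s, seq_len(n))) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-gene GC metrics table
#'
#' Applies [filter_cds] to every gene of a [gene_set] and computes GC3-50
#' and whole-gene GC3 for the passing genes. Genes without a stored CDS get
#' filter status `no_cds`.
#'
#' @param geneset a [gene_set].
#' @return data.frame with `gene_id`, `filter_status`, `n_codons`,
#'   `gc3_50`, `gc3_full` (NA where undefined).
#' @export
gene_gc_table <- function(geneset) {
  ids <- geneset$genes$gene_id
  out <- data.frame(gene_id = ids, filter_status = "no_cds",
                    n_codons = NA_integer_, gc3_50 = NA_real_,
                    gc3_full = NA_real_, stringsAsFactors = FALSE)
  has <- ids %in% names(geneset$cds)
  if (!any(has)) return(out)
  cds <- unname(geneset$cds[ids[has]])
  out$filter_status[has] <- filter_cds(cds)
  out$n_codons[has] <- nchar(cds) %/% 3L
  pass <- out$filter_status == "pass"
  pass_cds <- unname(geneset$cds[ids[pass]])
  out$gc3_50[pass] <- gc3_50(pass_cds)
  out$gc3_full[pass] <- gc3_full(pass_cds)
  out
}

#' Positional GC3 profile
#'
#' Mean G/C indicator of the third base of codon i across genes, for
#' i = 1..`max_codon`, with the number of contributing genes per index.
#' Genes shorter than i codons do not contribute at index i. After the CDS
#' filters, index 1 is always 1 (the start codon's G).
#'
#' @param cds character vector of passing coding sequences.
#' @param max_codon largest codon index profiled.
#' @return data.frame with `codon_index`, `mean_gc3`, `n_genes`.
#' @export
positional_gc3_profile <- function(cds, max_codon = 200L) {
  if (length(cds) == 0L) stop("at least one passing CDS required")
  cds <- toupper(cds)
  n_codons <- nchar(cds) %/% 3L
  mean_gc3 <- numeric(max_codon)
  n_genes <- integer(max_codon)
  for (i in seq_len(max_codon)) {
    with_i <- n_codons >= i
    n_genes[i] <- sum(with_i)
    if (n_genes[i] > 0L) {
      chars <- substring(cds[with_i], 3L * i, 3L * i)
      mean_gc3[i] <- mean(chars %in% c("G", "C"))
    } else {
      mean_gc3[i] <- NA_real_
    }
  }
  data.frame(codon_index = seq_len(max_codon), mean_gc3 = mean_gc3,
             n_genes = n_genes)
}
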
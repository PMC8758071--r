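#' Ordered gene-model container
#'
#' Bundles one species' gene models with their coding sequences and a dense
#' per-chromosome gene order. The ordinal (0-based rank of a gene among the
#' genes of its chromosome, sorted by start coordinate) is the coordinate
#' system all synteny operations work in.
#'
#' @param species_tag short species label, e.g. `"A"` or `"sbicolor"`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (1-based inclusive genomic coordinates).
#' @param cds named character vector of coding sequences (first splice
#'   variant, 5'->3' in coding orientation), named by `gene_id`. Genes
#'   without a CDS are allowed; downstream filters exclude them.
#' @param chrom_order character vector fixing chromosome order; defaults to
#'   order of first appearance in `genes`.
#'
#' @return An object of class `gene_set`: a list with elements
#'   `species_tag`, `genes` (with an added 0-based `ordinal` column),
#'   `cds`, and `chrom_order`.
#' @export
gene_set <- function(species_tag, genes, cds = character(0),
                     chrom_order = NULL) {
  stopifnot(is.character(species_tag), length(species_tag) == 1L)
  required <- c("gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id in gene table")
  }
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (is.null(chrom_order)) chrom_order <- unique(genes$chrom)
  # dense 0-based ordinals per chromosome; ties on start broken by gene_id
  ord <- order(match(genes$chrom, chrom_order), genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$ordinal <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                              FUN = seq_along) - 1L
  rownames(genes) <- NULL
  structure(
    list(species_tag = species_tag, genes = genes,
         cds = cds, chrom_order = chrom_order),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes on %d chromosome(s), %d with CDS\n",
              x$species_tag, nrow(x$genes), length(x$chrom_order),
              sum(x$genes$gene_id %in% names(x$cds))))
  invisible(x)
}

# Pull 'Key=value' out of a GFF3 attribute string; NA when absent.
gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "=[^;]*"),
                                            attrs))) > 0
  out[hit] <- sub(paste0("^(;)?", key, "="), "", sub("^;", "", m))
  out
}

#' Read gene models from GFF3 and CDS FASTA
#'
#' Builds a [gene_set] from a GFF3 annotation and a FASTA of coding
#' sequences. One gene model is kept per gene; when a gene has several mRNA
#' children the first by file order supplies the CDS ("first splice
#' variant"). FASTA records are matched by mRNA ID first, then by gene ID.
#'
#' @param gff3_path path to a GFF3 file with gene/mRNA features.
#' @param cds_fasta_path path to a FASTA of coding sequences, or `NULL` to
#'   load gene models without sequence.
#' @param species_tag short species label stored in the result.
#'
#' @return A [gene_set]. Genes whose CDS id cannot be matched in the FASTA
#'   are retained without a sequence (a warning reports the count); they are
#'   excluded later by the CDS filters.
#' @export
read_gene_models <- function(gff3_path, cds_fasta_path = NULL, species_tag) {
  lines <- readLines(gff3_path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d in %s (expected 9 tab-separated fields)",
                 bad, gff3_path))
  }
  if (!any(body)) {
    return(gene_set(species_tag,
                    data.frame(gene_id = character(0), chrom = character(0),
                               strand = character(0), start = integer(0),
                               end = integer(0))))
  }
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gr$type)
  is_gene <- type == "gene"
  if (!any(is_gene)) {
    return(gene_set(species_tag,
                    data.frame(gene_id = character(0), chrom = character(0),
                               strand = character(0), start = integer(0),
                               end = integer(0))))
  }
  genes <- data.frame(
    gene_id = as.character(gr$ID[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE
  )
  # first mRNA child per gene, in file order
  is_mrna <- type %in% c("mRNA", "transcript")
  mrna_id <- as.character(gr$ID[is_mrna])
  mrna_parent <- vapply(gr$Parent[is_mrna], function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  first_mrna <- mrna_id[!duplicated(mrna_parent)]
  names(first_mrna) <- mrna_parent[!duplicated(mrna_parent)]

  cds <- character(0)
  if (!is.null(cds_fasta_path)) {
    fa <- Biostrings::readDNAStringSet(cds_fasta_path)
    # FASTA headers may carry descriptions after whitespace
    names(fa) <- sub("\\s.*$", "", names(fa))
    fa_chr <- as.character(fa)
    key <- unname(first_mrna[genes$gene_id])
    key[is.na(key)] <- genes$gene_id[is.na(key)]
    hit_mrna <- key %in% names(fa)
    key[!hit_mrna & genes$gene_id %in% names(fa)] <-
      genes$gene_id[!hit_mrna & genes$gene_id %in% names(fa)]
    matched <- key %in% names(fa)
    if (any(!matched)) {
      warning(sprintf("%d gene(s) without matching CDS in %s; retained without sequence",
                      sum(!matched), cds_fasta_path))
    }
    cds <- fa_chr[key[matched]]
    names(cds) <- genes$gene_id[matched]
  }
  gene_set(species_tag, genes, cds = cds)
}

#' Read homolog anchor pairs
#'
#' Reads a tab-separated anchor file (BLAST outfmt-6-like; the first two
#' columns are gene ids in genome A and genome B, an optional third column a
#' similarity score). Pairs whose ids do not resolve in the supplied gene
#' sets are dropped with a reported count; duplicated pairs are collapsed.
#'
#' @param path path to the tab-separated anchor file.
#' @param geneset_a,geneset_b [gene_set]s the two id columns must resolve in.
#'
#' @return data.frame with columns `gene_a`, `gene_b`, `score` (NA when the
#'   file has no score column).
#' @export
read_anchor_pairs <- function(path, geneset_a, geneset_b) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (identical(tolower(as.character(tab[1L, 1L])), "gene_a")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  anchors <- data.frame(
    gene_a = as.character(tab[[1L]]),
    gene_b = as.character(tab[[2L]]),
    score = if (ncol(tab) >= 3L) suppressWarnings(as.numeric(tab[[3L]]))
            else NA_real_,
    stringsAsFactors = FALSE
  )
  ok <- anchors$gene_a %in% geneset_a$genes$gene_id &
        anchors$gene_b %in% geneset_b$genes$gene_id
  if (any(!ok)) {
    message(sprintf("read_anchor_pairs: dropped %d pair(s) with unresolvable ids",
                    sum(!ok)))
  }
  anchors <- anchors[ok, , drop = FALSE]
  anchors <- anchors[!duplicated(anchors[c("gene_a", "gene_b")]), ,
                     drop = FALSE]
  if (nrow(anchors) == 0L) stop("no resolvable anchor pairs in ", path)
  rownames(anchors) <- NULL
  anchors
}

#' Collapse a trinucleotide context to CG/CHG/CHH
#'
#' Maps a cytosine's three-base context string (read 5'->3' on the
#' cytosine's own strand) to the plant methylation context classes:
#' CG when base 2 is G, CHG when base 2 is H (A/C/T) and base 3 is G, CHH
#' when bases 2 and 3 are both H. Inputs already equal to `CG`, `CHG` or
#' `CHH` are passed through.
#'
#' @param context character vector of context strings.
#' @return character vector in `{CG, CHG, CHH}`; NA for undecidable strings.
#' @export
collapse_context <- function(context) {
  context <- toupper(context)
  out <- rep(NA_character_, length(context))
  out[context %in% c("CG", "CHG", "CHH")] <-
    context[context %in% c("CG", "CHG", "CHH")]
  todo <- is.na(out) & nchar(context) >= 2L & substr(context, 1L, 1L) == "C"
  b2 <- substr(context[todo], 2L, 2L)
  b3 <- substr(context[todo], 3L, 3L)
  res <- rep(NA_character_, sum(todo))
  res[b2 == "G"] <- "CG"
  h2 <- b2 %in% c("A", "C", "T")
  res[h2 & b3 == "G"] <- "CHG"
  res[h2 & b3 %in% c("A", "C", "T")] <- "CHH"
  out[todo] <- res
  out
}

#' Read per-cytosine bisulfite methylation calls
#'
#' Reads an allc-style table: chrom, 1-based position, strand, context
#' string, methylated-read count, total-read count (a 7th binomial-call
#' column, if present, is ignored). Three-letter contexts are collapsed to
#' CG/CHG/CHH. Zero-coverage rows are retained and flagged.
#'
#' @param path path to the tab-separated calls file.
#' @return data.frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `m_reads`, `total_reads`, `covered` (logical).
#' @export
read_methylation_calls <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (identical(tolower(as.character(tab[1L, 1L])), "chrom")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  calls <- data.frame(
    chrom = as.character(tab[[1L]]),
    pos = as.integer(tab[[2L]]),
    strand = as.character(tab[[3L]]),
    context = collapse_context(as.character(tab[[4L]])),
    m_reads = as.integer(tab[[5L]]),
    total_reads = as.integer(tab[[6L]]),
    stringsAsFactors = FALSE
  )
  bad <- which(calls$m_reads > calls$total_reads)
  if (length(bad) > 0L) {
    stop(sprintf("methylation call row %d (%s:%d): m_reads %d > total_reads %d",
                 bad[1L], calls$chrom[bad[1L]], calls$pos[bad[1L]],
                 calls$m_reads[bad[1L]], calls$total_reads[bad[1L]]))
  }
  if (anyNA(calls$context)) {
    stop("unrecognized methylation context string(s) in ", path)
  }
  calls$covered <- calls$total_reads > 0L
  calls
}

gene_table_columns <- c("gene_id", "species", "chrom", "ordinal", "syntenic",
                        "gc3_50", "gc3_full", "copy_class", "mCG", "mCHG",
                        "mCHH", "filter_status")

#' Write / read the per-gene metrics table
#'
#' The per-gene result record of the pipeline: synteny status, GC3-50 and
#' whole-gene GC3, copy-number class, and per-context weighted methylation
#' levels, one row per gene. Written as TSV with a fixed column set; floats
#' at 4 decimals; NA for undefined values. Lines starting with `#` are
#' treated as comments on read-back.
#'
#' @param records data.frame carrying the columns `gene_id`, `species`,
#'   `chrom`, `ordinal`, `syntenic` (0/1), `gc3_50`, `gc3_full`,
#'   `copy_class`, `mCG`, `mCHG`, `mCHH`, `filter_status`.
#' @param path output path.
#' @param header_comment optional character vector written as leading
#'   `#`-prefixed lines.
#' @return `write_gene_table` returns `path` invisibly; `read_gene_table`
#'   returns the parsed data.frame with numeric/integer column types
#'   restored.
#' @export
write_gene_table <- function(records, path, header_comment = NULL) {
  missing_cols <- setdiff(gene_table_columns, names(records))
  if (length(missing_cols) > 0L) {
    stop("gene table records lack columns: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- records[gene_table_columns]
  fmt4 <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  for (col in c("gc3_50", "gc3_full", "mCG", "mCHG", "mCHH")) {
    out[[col]] <- fmt4(as.numeric(out[[col]]))
  }
  out$syntenic <- as.integer(out$syntenic)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(gene_id = "character",
                                          species = "character",
                                          chrom = "character",
                                          copy_class = "character",
                                          filter_status = "character"))
  for (col in c("gc3_50", "gc3_full", "mCG", "mCHG", "mCHH")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab$ordinal <- as.integer(tab$ordinal)
  tab$syntenic <- as.integer(tab$syntenic)
  tab
}
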
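#' Prepare a genome for repeated hit counting
#'
#' Splits chromosome sequences into character vectors once so that
#' [count_genome_hits] can be called for many queries without re-parsing.
#'
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @return object of class `prepared_genome`.
#' @export
prepare_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome <- toupper(genome)
  structure(list(
    seqs = Biostrings::DNAStringSet(genome),
    chars = lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1L]]),
    lens = nchar(genome)
  ), class = "prepared_genome")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "",
                       fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Seed-and-extend ungapped search of one query (one strand) against all
# chromosomes. Exact seeds of `seed_len` nucleotides nominate candidate
# diagonals; each candidate is verified by ungapped identity over the
# aligned span. Returns hit spans in genome coordinates.
scan_query_hits <- function(query, prep, min_identity, min_coverage,
                            seed_len) {
  L <- nchar(query)
  n_seed <- L - seed_len + 1L
  seeds <- substring(query, seq_len(n_seed), seq_len(n_seed) + seed_len - 1L)
  useeds <- unique(seeds)
  offsets_of_seed <- split(seq_len(n_seed), match(seeds, useeds))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(useeds))
  qc <- strsplit(query, "", fixed = TRUE)[[1L]]
  min_alen <- ceiling(min_coverage * L)
  hits <- list()
  for (ci in seq_along(prep$seqs)) {
    m <- Biostrings::matchPDict(pd, prep$seqs[[ci]])
    starts <- Biostrings::startIndex(m)
    cand <- integer(0)
    for (si in seq_along(useeds)) {
      s <- starts[[si]]
      if (is.null(s) || length(s) == 0L) next
      for (qoff in offsets_of_seed[[si]]) cand <- c(cand, s - qoff + 1L)
    }
    cand <- sort(unique(cand))
    if (length(cand) == 0L) next
    tc <- prep$chars[[ci]]
    clen <- prep$lens[ci]
    for (o in cand) {
      g1 <- max(1L, o)
      g2 <- min(clen, o + L - 1L)
      alen <- g2 - g1 + 1L
      if (alen < min_alen) next
      q1 <- g1 - o + 1L
      ident <- sum(qc[q1:(q1 + alen - 1L)] == tc[g1:g2]) / alen
      if (ident >= min_identity) {
        hits[[length(hits) + 1L]] <- c(ci, g1, g2)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  h <- do.call(rbind, hits)
  data.frame(chrom = names(prep$seqs)[h[, 1L]], start = h[, 2L],
             end = h[, 3L], stringsAsFactors = FALSE)
}

# Merge hit spans into loci: spans on the same chromosome overlapping by at
# least half the shorter span are one locus (tandem near-identical repeats
# are not double-counted within a locus).
merge_loci <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  out <- list()
  for (chr in unique(hits$chrom)) {
    h <- hits[hits$chrom == chr, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    cur <- c(h$start[1L], h$end[1L])
    for (i in seq_len(nrow(h))[-1L]) {
      ov <- min(cur[2L], h$end[i]) - max(cur[1L], h$start[i]) + 1L
      w <- min(cur[2L] - cur[1L], h$end[i] - h$start[i]) + 1L
      if (ov >= 0.5 * w) {
        cur[2L] <- max(cur[2L], h$end[i])
      } else {
        out[[length(out) + 1L]] <- c(chr, cur)
        cur <- c(h$start[i], h$end[i])
      }
    }
    out[[length(out) + 1L]] <- c(chr, cur)
  }
  m <- do.call(rbind, out)
  data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
             end = as.integer(m[, 3L]), stringsAsFactors = FALSE)
}

#' Count genomic copies of a gene's 5' end
#'
#' Counts the non-overlapping genomic loci at which the first 150 bp of a
#' gene's coding sequence align at high stringency, on either strand. An
#' ungapped seed-and-extend alignment (exact seed of `seed_len`
#' nucleotides) must reach at least `min_identity` over at least
#' `min_coverage` of the query; hits whose spans overlap by half or more
#' are merged into one locus. The identity/coverage gate operationalizes a
#' high-stringency BLASTN search (E < 1e-30, roughly >90% identity).
#' The gene's own locus matches itself, so a genic query always yields at
#' least 1.
#'
#' @param query the query sequence (at least 50 bp; typically the first
#'   150 bp of a CDS).
#' @param genome a [prepare_genome] object, or a named character vector /
#'   `DNAStringSet` of chromosome sequences.
#' @param min_identity minimum ungapped identity over the aligned span.
#' @param min_coverage minimum fraction of the query that must align.
#' @param seed_len exact-seed length nominating candidate loci.
#' @return integer number of distinct matching loci.
#' @export
count_genome_hits <- function(query, genome, min_identity = 0.9,
                              min_coverage = 0.9, seed_len = 12L) {
  query <- toupper(query)
  if (nchar(query) < 50L) stop("query shorter than 50 bp")
  if (!inherits(genome, "prepared_genome")) genome <- prepare_genome(genome)
  fwd <- scan_query_hits(query, genome, min_identity, min_coverage, seed_len)
  rev <- scan_query_hits(revcomp(query), genome, min_identity, min_coverage,
                         seed_len)
  nrow(merge_loci(rbind(fwd, rev)))
}

#' Count hits from a precomputed BLAST tabular file
#'
#' Alternative to the internal matcher: counts, per query, tabular BLASTN
#' hits below an E-value ceiling, with the same locus-merging rule as
#' [count_genome_hits].
#'
#' @param tab data.frame in BLAST outfmt-6 layout (columns `qseqid`,
#'   `sseqid`, ..., `sstart`, `send`, `evalue` — columns 1, 2, 9, 10, 11
#'   are used).
#' @param max_evalue E-value ceiling (default 1e-30).
#' @return data.frame with `gene_id`, `n_hits`.
#' @export
count_hits_blast_tab <- function(tab, max_evalue = 1e-30) {
  stopifnot(ncol(tab) >= 11L)
  df <- data.frame(qseqid = as.character(tab[[1L]]),
                   sseqid = as.character(tab[[2L]]),
                   sstart = as.integer(tab[[9L]]),
                   send = as.integer(tab[[10L]]),
                   evalue = as.numeric(tab[[11L]]),
                   stringsAsFactors = FALSE)
  df <- df[df$evalue < max_evalue, , drop = FALSE]
  lo <- pmin(df$sstart, df$send)
  hi <- pmax(df$sstart, df$send)
  df$start <- lo
  df$end <- hi
  counts <- vapply(split(df, df$qseqid), function(h) {
    nrow(merge_loci(data.frame(chrom = h$sseqid, start = h$start,
                               end = h$end, stringsAsFactors = FALSE)))
  }, integer(1))
  data.frame(gene_id = names(counts), n_hits = unname(counts),
             stringsAsFactors = FALSE)
}

#' Bin copy number into repetitiveness classes
#'
#' `1` copy is `single`, `2-9` copies `moderate`, `10+` copies
#' `repetitive`.
#'
#' @param n_hits integer vector of locus counts (all at least 1: a genic
#'   query always hits its own locus).
#' @return character vector of class labels.
#' @export
bin_copy_number <- function(n_hits) {
  if (any(is.na(n_hits)) || any(n_hits < 1L)) {
    stop("n_hits must be >= 1 (the gene's own locus always counts)")
  }
  cls <- rep("moderate", length(n_hits))
  cls[n_hits == 1L] <- "single"
  cls[n_hits >= 10L] <- "repetitive"
  cls
}

#' Per-gene copy-number table
#'
#' Runs [count_genome_hits] on the first 150 bp of each gene's CDS against
#' the genome assembly and bins the counts. Genes without a CDS of at least
#' 50 bp get NA.
#'
#' @param geneset a [gene_set].
#' @param genome chromosome sequences (see [count_genome_hits]).
#' @param query_len length of the 5' query (default 150 bp).
#' @inheritParams count_genome_hits
#' @return data.frame with `gene_id`, `n_hits`, `copy_class`.
#' @export
gene_copy_table <- function(geneset, genome, query_len = 150L,
                            min_identity = 0.9, min_coverage = 0.9,
                            seed_len = 12L) {
  if (!inherits(genome, "prepared_genome")) genome <- prepare_genome(genome)
  ids <- geneset$genes$gene_id
  cds <- geneset$cds[ids]
  usable <- !is.na(cds) & nchar(cds) >= 50L
  n_hits <- rep(NA_integer_, length(ids))
  if (any(usable)) {
    q_fwd <- toupper(substr(cds[usable], 1L, query_len))
    queries <- c(q_fwd, revcomp(q_fwd))
    qgene <- rep(which(usable), 2L)
    # joint seed dictionary over every query (both strands): one
    # Aho-Corasick pass per chromosome instead of one per gene
    qlen <- nchar(queries)
    n_seed <- qlen - seed_len + 1L
    seed_tab <- data.frame(
      qi = rep(seq_along(queries), n_seed),
      qoff = unlist(lapply(n_seed, seq_len)),
      stringsAsFactors = FALSE)
    seed_tab$seed <- substring(queries[seed_tab$qi], seed_tab$qoff,
                               seed_tab$qoff + seed_len - 1L)
    useed <- unique(seed_tab$seed)
    seed_tab$si <- match(seed_tab$seed, useed)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(useed))
    qchars <- strsplit(queries, "", fixed = TRUE)
    hit_rows <- list()
    for (ci in seq_along(genome$seqs)) {
      m <- Biostrings::matchPDict(pd, genome$seqs[[ci]])
      starts <- Biostrings::startIndex(m)
      n_occ <- lengths(starts)
      if (sum(n_occ) == 0L) next
      occ <- data.frame(si = rep(seq_along(starts), n_occ),
                        start = unlist(starts))
      cand <- merge(occ, seed_tab[c("si", "qi", "qoff")], by = "si")
      cand$offset <- cand$start - cand$qoff + 1L
      cand <- unique(cand[c("qi", "offset")])
      tc <- genome$chars[[ci]]
      clen <- genome$lens[ci]
      for (r in seq_len(nrow(cand))) {
        qi <- cand$qi[r]; o <- cand$offset[r]
        L <- qlen[qi]
        g1 <- max(1L, o); g2 <- min(clen, o + L - 1L)
        alen <- g2 - g1 + 1L
        if (alen < ceiling(min_coverage * L)) next
        q1 <- g1 - o + 1L
        ident <- sum(qchars[[qi]][q1:(q1 + alen - 1L)] == tc[g1:g2]) / alen
        if (ident >= min_identity) {
          hit_rows[[length(hit_rows) + 1L]] <- c(qgene[qi], ci, g1, g2)
        }
      }
    }
    if (length(hit_rows) > 0L) {
      h <- as.data.frame(do.call(rbind, hit_rows))
      names(h) <- c("gene", "chrom", "start", "end")
      h$chrom <- names(genome$seqs)[h$chrom]
      for (gi in unique(h$gene)) {
        n_hits[gi] <- nrow(merge_loci(h[h$gene == gi,
                                        c("chrom", "start", "end")]))
      }
    }
    n_hits[usable & is.na(n_hits)] <- 0L  # no locus found (non-genic query)
  }
  copy_class <- rep(NA_character_, length(ids))
  ok <- !is.na(n_hits) & n_hits >= 1L
  copy_class[ok] <- bin_copy_number(n_hits[ok])
  data.frame(gene_id = ids, n_hits = n_hits, copy_class = copy_class,
             stringsAsFactors = FALSE)
}
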
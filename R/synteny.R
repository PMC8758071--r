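#' Chaining parameters for collinear block detection
#'
#' @param min_anchors minimum number of anchor pairs a reported block must
#'   chain (blocks of at least 7 conserved gene pairs by default).
#' @param max_gap largest gene-rank gap allowed between consecutive anchors
#'   of a chain, in each genome separately.
#' @param collapse_tandems collapse tandem arrays of homologs to a single
#'   representative anchor before chaining.
#' @param tandem_window ordinal distance within which same-chromosome genes
#'   sharing an anchor partner are considered one tandem array.
#' @return list of class `chain_params`.
#' @export
chain_params <- function(min_anchors = 7L, max_gap = 20L,
                         collapse_tandems = TRUE, tandem_window = 10L) {
  stopifnot(min_anchors >= 2L, max_gap >= 1L, tandem_window >= 1L)
  structure(list(min_anchors = as.integer(min_anchors),
                 max_gap = as.integer(max_gap),
                 collapse_tandems = isTRUE(collapse_tandems),
                 tandem_window = as.integer(tandem_window)),
            class = "chain_params")
}

# Attach chromosome and ordinal of both genomes to an anchor table.
# Identity anchors (a gene matched to itself in a self-comparison) are
# removed so self-synteny reflects ancient duplication, not the trivial
# diagonal.
resolve_anchors <- function(anchors, geneset_a, geneset_b) {
  ia <- match(anchors$gene_a, geneset_a$genes$gene_id)
  ib <- match(anchors$gene_b, geneset_b$genes$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("anchor with unresolvable gene id")
  df <- data.frame(
    gene_a = anchors$gene_a, gene_b = anchors$gene_b,
    chrom_a = geneset_a$genes$chrom[ia], ord_a = geneset_a$genes$ordinal[ia],
    chrom_b = geneset_b$genes$chrom[ib], ord_b = geneset_b$genes$ordinal[ib],
    stringsAsFactors = FALSE
  )
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  df <- df[!duplicated(df[c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Union-find over integer ids.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Collapse tandem arrays of homologs to representative anchors
#'
#' Genes on the same chromosome within `tandem_window` ordinals of each
#' other that anchor to a common partner are treated as one tandem array and
#' represented by the lowest-ordinal member, on each side of the comparison.
#' The returned maps let the final synteny status of a representative be
#' propagated back to every collapsed member.
#'
#' @param anchors data.frame with `gene_a`, `gene_b` columns.
#' @param geneset_a,geneset_b the two [gene_set]s.
#' @param params [chain_params]; with `collapse_tandems = FALSE` the input
#'   is returned unchanged (identity maps).
#' @return list with `anchors` (reduced anchor table), `rep_a`, `rep_b`
#'   (named character vectors mapping every anchored gene to its
#'   representative; identity for genes not in an array).
#' @export
collapse_tandem_arrays <- function(anchors, geneset_a, geneset_b,
                                   params = chain_params()) {
  res <- resolve_anchors(anchors, geneset_a, geneset_b)
  identity_map <- function(ids) stats::setNames(ids, ids)
  if (!params$collapse_tandems || nrow(res) == 0L) {
    return(list(anchors = res,
                rep_a = identity_map(unique(res$gene_a)),
                rep_b = identity_map(unique(res$gene_b))))
  }
  collapse_side <- function(res, gene_col, chrom_col, ord_col, partner_col) {
    ids <- unique(res[[gene_col]])
    idx <- match(res[[gene_col]], ids)
    chrom <- res[[chrom_col]][match(ids, res[[gene_col]])]
    ordn <- res[[ord_col]][match(ids, res[[gene_col]])]
    parent <- seq_along(ids)
    # link genes that share a partner, sit on the same chromosome and are
    # within the tandem window of each other
    by_partner <- split(seq_len(nrow(res)), res[[partner_col]])
    for (rows in by_partner) {
      g <- unique(idx[rows])
      if (length(g) < 2L) next
      g <- g[order(chrom[g], ordn[g])]
      for (k in seq_len(length(g) - 1L)) {
        i <- g[k]; j <- g[k + 1L]
        if (chrom[i] == chrom[j] &&
            abs(ordn[j] - ordn[i]) <= params$tandem_window) {
          ri <- uf_find(parent, i); rj <- uf_find(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    root <- vapply(seq_along(ids), function(i) uf_find(parent, i), integer(1))
    # representative = lowest-ordinal member of each component
    rep_idx <- vapply(split(seq_along(ids), root),
                      function(g) g[which.min(ordn[g])], integer(1))
    rep_of <- ids[rep_idx[as.character(root)]]
    stats::setNames(rep_of, ids)
  }
  rep_a <- collapse_side(res, "gene_a", "chrom_a", "ord_a", "gene_b")
  rep_b <- collapse_side(res, "gene_b", "chrom_b", "ord_b", "gene_a")
  res$gene_a <- unname(rep_a[res$gene_a])
  res$gene_b <- unname(rep_b[res$gene_b])
  res <- res[!duplicated(res[c("gene_a", "gene_b")]), , drop = FALSE]
  # refresh coordinates of representatives
  res <- resolve_anchors(res[c("gene_a", "gene_b")], geneset_a, geneset_b)
  list(anchors = res, rep_a = rep_a, rep_b = rep_b)
}

# Longest chain (by anchor count) through anchors of one chromosome pair and
# one orientation. `sign` is +1 for ascending, -1 for descending ord_b.
# Returns indices (into oa/ob) of the best chain, deterministically
# tie-broken toward earlier anchors in (ord_a, sign * ord_b) order.
longest_chain <- function(oa, ob, sign, max_gap) {
  n <- length(oa)
  if (n == 0L) return(integer(0))
  o <- order(oa, sign * ob)
  oa <- oa[o]; ob <- ob[o]
  dp <- rep(1L, n); pred <- rep(0L, n)
  for (i in seq_len(n)) {
    da <- oa[i] - oa
    db <- (ob[i] - ob) * sign
    cand <- which(da > 0L & da <= max_gap & db > 0L & db <= max_gap)
    if (length(cand) > 0L) {
      j <- cand[which.max(dp[cand])]
      dp[i] <- dp[j] + 1L
      pred[i] <- j
    }
  }
  k <- which.max(dp)
  chain <- integer(0)
  while (k != 0L) {
    chain <- c(k, chain)
    k <- pred[k]
  }
  o[chain]
}

#' Chain anchors into collinear syntenic blocks
#'
#' Per chromosome pair and orientation, a longest-chain dynamic program
#' links anchors whose gene-rank deltas are positive and at most `max_gap`
#' in both genomes (with the orientation's sign in genome B). Maximal chains
#' are extracted best-score-first; each anchor is assigned to at most one
#' block; chains shorter than `min_anchors` are discarded.
#'
#' @param anchors data.frame with `gene_a`, `gene_b` columns (tandem
#'   collapsing, if wanted, is applied by the caller beforehand).
#' @param geneset_a,geneset_b the two [gene_set]s supplying gene order.
#' @param params [chain_params].
#' @return object of class `synteny_blocks`: list with `blocks` (one row
#'   per block: `block_id`, `chrom_a`, `chrom_b`, `orientation`,
#'   `n_anchors`, `a_start`, `a_end`, `b_start`, `b_end`) and `anchors`
#'   (anchor-to-block assignment with ordinals).
#' @export
chain_anchors <- function(anchors, geneset_a, geneset_b,
                          params = chain_params()) {
  res <- resolve_anchors(anchors, geneset_a, geneset_b)
  empty <- list(
    blocks = data.frame(block_id = character(0), chrom_a = character(0),
                        chrom_b = character(0), orientation = character(0),
                        n_anchors = integer(0), a_start = integer(0),
                        a_end = integer(0), b_start = integer(0),
                        b_end = integer(0), stringsAsFactors = FALSE),
    anchors = data.frame(block_id = character(0), gene_a = character(0),
                         gene_b = character(0), ord_a = integer(0),
                         ord_b = integer(0), stringsAsFactors = FALSE))
  class(empty) <- "synteny_blocks"
  if (nrow(res) == 0L) return(empty)

  pair_key <- paste(res$chrom_a, res$chrom_b, sep = "\r")
  out_blocks <- list(); out_anchors <- list()
  for (key in sort(unique(pair_key))) {
    sub <- res[pair_key == key, , drop = FALSE]
    repeat {
      if (nrow(sub) < params$min_anchors) break
      ch_plus <- longest_chain(sub$ord_a, sub$ord_b, +1L, params$max_gap)
      ch_minus <- longest_chain(sub$ord_a, sub$ord_b, -1L, params$max_gap)
      if (length(ch_plus) >= length(ch_minus)) {
        chain <- ch_plus; orient <- "+"
      } else {
        chain <- ch_minus; orient <- "-"
      }
      if (length(chain) < params$min_anchors) break
      blk <- sub[chain, , drop = FALSE]
      out_blocks[[length(out_blocks) + 1L]] <- data.frame(
        chrom_a = blk$chrom_a[1L], chrom_b = blk$chrom_b[1L],
        orientation = orient, n_anchors = nrow(blk),
        a_start = min(blk$ord_a), a_end = max(blk$ord_a),
        b_start = min(blk$ord_b), b_end = max(blk$ord_b),
        stringsAsFactors = FALSE)
      out_anchors[[length(out_anchors) + 1L]] <- blk
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  if (length(out_blocks) == 0L) return(empty)
  blocks <- do.call(rbind, out_blocks)
  ord <- order(match(blocks$chrom_a, geneset_a$chrom_order), blocks$a_start,
               blocks$chrom_b, blocks$b_start)
  blocks <- blocks[ord, , drop = FALSE]
  blocks <- cbind(block_id = sprintf("B%04d", seq_len(nrow(blocks))), blocks,
                  stringsAsFactors = FALSE)
  anchors_out <- do.call(rbind, lapply(seq_along(ord), function(i) {
    blk <- out_anchors[[ord[i]]]
    data.frame(block_id = blocks$block_id[i], gene_a = blk$gene_a,
               gene_b = blk$gene_b, ord_a = blk$ord_a, ord_b = blk$ord_b,
               stringsAsFactors = FALSE)
  }))
  rownames(blocks) <- rownames(anchors_out) <- NULL
  structure(list(blocks = blocks, anchors = anchors_out),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("<synteny_blocks> %d block(s), %d anchor(s)\n",
              nrow(x$blocks), nrow(x$anchors)))
  invisible(x)
}

#' Detect synteny between two gene orders
#'
#' Convenience wrapper running tandem collapsing, anchor chaining and
#' member propagation for one genome comparison.
#'
#' @inheritParams collapse_tandem_arrays
#' @return list with `blocks` (a `synteny_blocks` object), `members_a` and
#'   `members_b` (character vectors of gene ids found inside blocks,
#'   including collapsed tandem members).
#' @export
detect_synteny <- function(anchors, geneset_a, geneset_b,
                           params = chain_params()) {
  col <- collapse_tandem_arrays(anchors, geneset_a, geneset_b, params)
  blocks <- chain_anchors(col$anchors, geneset_a, geneset_b, params)
  in_a <- unique(blocks$anchors$gene_a)
  in_b <- unique(blocks$anchors$gene_b)
  members_a <- names(col$rep_a)[col$rep_a %in% in_a]
  members_b <- names(col$rep_b)[col$rep_b %in% in_b]
  list(blocks = blocks,
       members_a = unique(members_a), members_b = unique(members_b))
}

#' Classify genes as syntenic or non-syntenic
#'
#' A gene is syntenic when it lies inside a detected collinear block (or is
#' a collapsed tandem member of a block anchor) in at least one genome
#' comparison; all other genes are non-syntenic.
#'
#' @param geneset the focal species' [gene_set].
#' @param memberships named list, one element per comparison tag, each a
#'   character vector of focal-species gene ids found inside blocks of that
#'   comparison (`members_a`/`members_b` from [detect_synteny]).
#' @return data.frame with `gene_id`, `syntenic` (logical), `n_support`,
#'   `supporting` (comma-separated comparison tags).
#' @export
classify_synteny <- function(geneset, memberships) {
  if (nrow(geneset$genes) == 0L) stop("empty gene set")
  if (length(memberships) == 0L || is.null(names(memberships))) {
    stop("memberships must be a named list with one element per comparison")
  }
  ids <- geneset$genes$gene_id
  support <- matrix(FALSE, nrow = length(ids), ncol = length(memberships),
                    dimnames = list(ids, names(memberships)))
  for (tag in names(memberships)) {
    support[ids %in% memberships[[tag]], tag] <- TRUE
  }
  n_support <- rowSums(support)
  data.frame(
    gene_id = ids,
    syntenic = n_support > 0L,
    n_support = as.integer(n_support),
    supporting = apply(support, 1L, function(r)
      paste(colnames(support)[r], collapse = ",")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-comparison syntenic gene counts and their union
#'
#' @param memberships named list of per-comparison syntenic gene-id vectors
#'   for one focal species.
#' @return data.frame with one row per comparison plus a `union` row; the
#'   union count is at least every single-comparison count.
#' @export
synteny_summary_matrix <- function(memberships) {
  if (length(memberships) == 0L) stop("at least one comparison required")
  counts <- vapply(memberships, function(m) length(unique(m)), integer(1))
  data.frame(
    comparison = c(names(memberships), "union"),
    n_syntenic = c(counts, length(unique(unlist(memberships)))),
    stringsAsFactors = FALSE
  )
}

#' Validate the collinearity contract of detected blocks
#'
#' Asserts strict double monotonicity, the gap bound, the block-size floor
#' and anchor disjointness on a `synteny_blocks` object. Used by tests and
#' as an internal sanity check.
#'
#' @param blocks a `synteny_blocks` object.
#' @param params the [chain_params] the blocks were built with.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_blocks <- function(blocks, params) {
  a <- blocks$anchors
  if (nrow(a) == 0L) return(invisible(TRUE))
  if (anyDuplicated(a[c("gene_a", "gene_b")])) {
    stop("anchor assigned to two blocks")
  }
  for (bid in unique(a$block_id)) {
    blk <- a[a$block_id == bid, , drop = FALSE]
    orient <- blocks$blocks$orientation[blocks$blocks$block_id == bid]
    blk <- blk[order(blk$ord_a), , drop = FALSE]
    da <- diff(blk$ord_a)
    db <- diff(blk$ord_b) * if (orient == "+") 1L else -1L
    if (nrow(blk) < params$min_anchors) stop("block below min_anchors")
    if (any(da <= 0L | da > params$max_gap)) stop("gap violation in genome A")
    if (any(db <= 0L | db > params$max_gap)) stop("gap violation in genome B")
  }
  invisible(TRUE)
}
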
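#' Configuration for the synthetic genome-pair generator
#'
#' The generator evolves an ancestral gene order down two lineages with
#' inversions, translocations, tandem and dispersed duplications and gene
#' losses, then lays the genes out on chromosome sequences and simulates
#' read-level bisulfite data. Genes belong to one of two heritable classes:
#' `prone` (duplication-prone; low third-codon GC, high methylation) and
#' `resistant` (rarely duplicated; high third-codon GC, low methylation),
#' reproducing the joint duplication/GC/methylation structure the analysis
#' is built to detect — including the bimodal grass-like GC3-50
#' distribution with one mode in the low 40s and one at 90-94%.
#'
#' @param seed integer seed; every stage derives its own substream from it,
#'   so outputs are bit-reproducible and adding a stage does not perturb
#'   earlier draws.
#' @param n_chromosomes,genes_per_chromosome ancestral genome shape.
#' @param fraction_duplication_prone fraction of ancestral genes in the
#'   duplication-prone class.
#' @param n_inversions,n_translocations,n_dispersed_duplications,n_tandem_duplications,n_losses
#'   event counts applied to each lineage independently.
#' @param loss_after_duplication probability that a dispersed duplication
#'   is followed by loss of the original copy (duplication-then-loss moves
#'   a gene and breaks its synteny).
#' @param duplication_class_odds odds with which dispersed-duplication
#'   sources are drawn from the prone class relative to the resistant one.
#' @param gc3_target_high,gc3_target_low per-class probability that a third
#'   codon position is G/C (`resistant` uses the high target).
#' @param meth_beta per-class, per-context Beta parameters for the true
#'   methylation level of a gene's 5' region.
#' @param read_depth bisulfite read depth per cytosine.
#' @param cds_codons length range (codons) of generated coding sequences.
#' @param spacer_len length of the random intergenic spacer.
#' @param event_span length range (genes) of inverted/translocated
#'   segments.
#' @param min_block minimum run length (gene pairs) for a ground-truth
#'   syntenic block.
#' @param max_gap gene-rank gap tolerated inside a ground-truth block
#'   (matching the chaining contract).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_chromosomes = 2L,
                       genes_per_chromosome = 300L,
                       fraction_duplication_prone = 0.4,
                       n_inversions = 4L,
                       n_translocations = 2L,
                       n_dispersed_duplications = 55L,
                       n_tandem_duplications = 20L,
                       n_losses = 45L,
                       loss_after_duplication = 0.5,
                       duplication_class_odds = 4,
                       gc3_target_high = 0.92,
                       gc3_target_low = 0.40,
                       meth_beta = list(
                         prone = list(CG = c(3, 7), CHG = c(1, 9),
                                      CHH = c(0.4, 19.6)),
                         resistant = list(CG = c(1, 9), CHG = c(0.3, 19.7),
                                          CHH = c(0.1, 19.9))),
                       read_depth = 30L,
                       cds_codons = c(60L, 150L),
                       spacer_len = 300L,
                       event_span = c(10L, 30L),
                       min_block = 7L,
                       max_gap = 20L) {
  cfg <- as.list(environment())
  stopifnot(cfg$fraction_duplication_prone >= 0,
            cfg$fraction_duplication_prone <= 1,
            cfg$loss_after_duplication >= 0, cfg$loss_after_duplication <= 1,
            cfg$gc3_target_high >= 0, cfg$gc3_target_high <= 1,
            cfg$gc3_target_low >= 0, cfg$gc3_target_low <= 1,
            all(unlist(cfg[grep("^n_", names(cfg))]) >= 0),
            cfg$min_block >= 2L, cfg$read_depth >= 0L)
  structure(cfg, class = "sim_config")
}

#' Reduced configuration for a small packaged fixture
#'
#' Two chromosomes of 60 genes with proportionally scaled-down event
#' counts; used for quick examples and light-weight tests.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config].
#' @return a [sim_config].
#' @export
small_sim_config <- function(seed = 42L, ...) {
  defaults <- list(seed = seed, genes_per_chromosome = 60L,
                   n_inversions = 1L, n_translocations = 0L,
                   n_dispersed_duplications = 11L, n_tandem_duplications = 4L,
                   n_losses = 9L, event_span = c(8L, 12L))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

#' Scaled-up configuration for decisive end-to-end statistics
#'
#' The default genome (2 x 300 genes) demonstrates the joint
#' duplication/GC/methylation pattern but leaves the non-syntenic group
#' small (roughly 120 genes). This configuration scales the genome and all
#' event counts four-fold at identical per-gene event densities, giving
#' rank-sum comparisons enough genes per group to resolve the syntenic vs
#' non-syntenic GC3-50 contrast at very small p.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config].
#' @return a [sim_config].
#' @export
large_sim_config <- function(seed = 42L, ...) {
  defaults <- list(seed = seed, genes_per_chromosome = 1200L,
                   n_inversions = 16L, n_translocations = 8L,
                   n_dispersed_duplications = 220L,
                   n_tandem_duplications = 80L, n_losses = 180L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Deterministic per-stage substream seed (kept well below 2^31).
stage_seed <- function(seed, k) {
  (as.integer(seed) %% 19999999L) * 100L + as.integer(k)
}

#' Generate coding sequences for a gene class
#'
#' ATG start; first and second codon positions drawn from a codon-safe
#' alphabet that can never complete a stop codon (after a T in position 1,
#' position 2 avoids A and G); third positions are G or C (equiprobably)
#' with probability equal to the class GC3 target, else A or T. No
#' ambiguous bases are produced, so generated genes always pass the CDS
#' filters.
#'
#' @param class_label `"prone"` (low-GC class) or `"resistant"` (high-GC).
#' @param config a [sim_config]; the class GC3 targets and length range
#'   come from it.
#' @param n number of sequences.
#' @param n_codons optional fixed codon count overriding the config range.
#' @return character vector of `n` coding sequences.
#' @export
generate_cds <- function(class_label, config = sim_config(), n = 1L,
                         n_codons = NULL) {
  stopifnot(class_label %in% c("prone", "resistant"))
  target <- if (class_label == "resistant") config$gc3_target_high
            else config$gc3_target_low
  rng <- config$cds_codons
  vapply(seq_len(n), function(i) {
    k <- if (!is.null(n_codons)) n_codons
         else sample(rng[1L]:rng[2L], 1L)
    k2 <- k - 1L   # codons after the ATG
    p1 <- sample(c("A", "C", "G", "T"), k2, replace = TRUE)
    p2_any <- sample(c("A", "C", "G", "T"), k2, replace = TRUE)
    p2_safe <- sample(c("C", "T"), k2, replace = TRUE)
    p2 <- ifelse(p1 == "T", p2_safe, p2_any)
    strong <- sample(c("G", "C"), k2, replace = TRUE)
    weak <- sample(c("A", "T"), k2, replace = TRUE)
    p3 <- ifelse(stats::runif(k2) < target, strong, weak)
    paste0("ATG", paste0(p1, p2, p3, collapse = ""))
  }, character(1))
}

# ---- lineage evolution -----------------------------------------------------

# sample() treats a length-1 numeric vector as 1:n; index-based sampling
# avoids that pitfall for token vectors.
sample_vec <- function(x, n) x[sample.int(length(x), n)]

# A lineage genome is a list of integer vectors (tokens per chromosome)
# plus a registry describing each token.
new_registry <- function(ancestor) {
  data.frame(token = seq_len(nrow(ancestor)),
             anc_id = ancestor$anc_id,
             class = ancestor$class,
             origin = "ancestral",
             source_token = NA_integer_,
             stringsAsFactors = FALSE)
}

random_position <- function(chroms) {
  lens <- lengths(chroms)
  ci <- sample.int(length(chroms), 1L, prob = lens + 1L)
  list(chrom = ci, at = sample.int(lens[ci] + 1L, 1L) - 1L) # insert after `at`
}

insert_token <- function(chroms, ci, at, token) {
  v <- chroms[[ci]]
  chroms[[ci]] <- append(v, token, after = at)
  chroms
}

# Pre-draw inversion/translocation regions for both lineages from one
# shared ancestral-coordinate pool, keeping every breakpoint at least one
# block length away from every other breakpoint and from chromosome ends.
# This keeps ground-truth blocks well-defined: every segment between
# breakpoints is itself at least min_block genes long in both lineages.
plan_rearrangements <- function(config, seed) {
  if (config$n_inversions + config$n_translocations == 0L) {
    return(list(A = list(), B = list()))
  }
  set.seed(seed)
  gpc <- config$genes_per_chromosome
  margin <- config$min_block + 1L
  if (any(config$event_span + 2L * margin > gpc)) {
    stop("rearrangement spans exceed chromosome size")
  }
  reserved <- list()   # per chromosome: matrix of reserved [lo, hi]
  free_starts <- function(ci, width) {
    starts <- (margin + 1L):(gpc - margin - width + 1L)
    r <- reserved[[as.character(ci)]]
    if (is.null(r)) return(starts)
    ok <- vapply(starts, function(lo) {
      hi <- lo + width - 1L
      all(hi + margin < r[, 1L] | lo - margin > r[, 2L])
    }, logical(1))
    starts[ok]
  }
  reserve <- function(ci, lo, hi) {
    key <- as.character(ci)
    reserved[[key]] <<- rbind(reserved[[key]], c(lo, hi))
  }
  draw_region <- function(width) {
    for (ci in sample.int(config$n_chromosomes)) {
      fs <- free_starts(ci, width)
      if (length(fs) > 0L) {
        start <- fs[sample.int(length(fs), 1L)]
        reserve(ci, start, start + width - 1L)
        return(list(chrom = ci, start = start, end = start + width - 1L))
      }
    }
    stop("could not place rearrangement: too many events for genome size")
  }
  draw_span <- function() {
    draw_region(sample(config$event_span[1L]:config$event_span[2L], 1L))
  }
  draw_point <- function() {
    r <- draw_region(1L)
    list(chrom = r$chrom, pos = r$start)
  }
  token_at <- function(ci, pos) (ci - 1L) * gpc + pos
  plan <- list(A = list(), B = list())
  for (lg in c("A", "B")) {
    for (i in seq_len(config$n_inversions)) {
      sp <- draw_span()
      plan[[lg]][[length(plan[[lg]]) + 1L]] <- list(
        type = "inversion",
        tokens = token_at(sp$chrom, sp$start):token_at(sp$chrom, sp$end))
    }
    for (i in seq_len(config$n_translocations)) {
      sp <- draw_span()
      pt <- draw_point()
      plan[[lg]][[length(plan[[lg]]) + 1L]] <- list(
        type = "translocation",
        tokens = token_at(sp$chrom, sp$start):token_at(sp$chrom, sp$end),
        insert_after = token_at(pt$chrom, pt$pos))
    }
  }
  plan
}

evolve_lineage <- function(ancestor, config, seed, rearr_plan = list()) {
  set.seed(seed)
  gpc <- config$genes_per_chromosome
  chroms <- split(seq_len(nrow(ancestor)),
                  rep(seq_len(config$n_chromosomes), each = gpc))
  names(chroms) <- NULL
  reg <- new_registry(ancestor)
  genome_size <- sum(lengths(chroms))
  if (config$n_losses + config$n_dispersed_duplications >= genome_size) {
    stop("duplication/loss counts exceed genome size")
  }
  events <- list()
  log_event <- function(type, detail) {
    events[[length(events) + 1L]] <<- data.frame(type = type, detail = detail,
                                                 stringsAsFactors = FALSE)
  }

  # rearrangements first (planned in ancestral coordinates; the planner
  # keeps event regions disjoint, so each token span is still contiguous
  # when its event executes)
  locate <- function(tok) {
    ci <- which(vapply(chroms, function(v) tok %in% v, logical(1)))[1L]
    list(chrom = ci, at = match(tok, chroms[[ci]]))
  }
  for (ev in rearr_plan) {
    if (ev$type == "inversion") {
      p1 <- locate(ev$tokens[1L])
      p2 <- locate(ev$tokens[length(ev$tokens)])
      stopifnot(p1$chrom == p2$chrom)
      idx <- p1$at:p2$at
      chroms[[p1$chrom]][idx] <- rev(chroms[[p1$chrom]][idx])
      log_event("inversion", sprintf("chr%d:%d-%d", p1$chrom, p1$at, p2$at))
    } else if (ev$type == "translocation") {
      p1 <- locate(ev$tokens[1L])
      p2 <- locate(ev$tokens[length(ev$tokens)])
      stopifnot(p1$chrom == p2$chrom)
      seg <- chroms[[p1$chrom]][p1$at:p2$at]
      chroms[[p1$chrom]] <- chroms[[p1$chrom]][-(p1$at:p2$at)]
      tgt <- locate(ev$insert_after)
      chroms[[tgt$chrom]] <- append(chroms[[tgt$chrom]], seg,
                                    after = tgt$at)
      log_event("translocation",
                sprintf("chr%d:%d+%d->chr%d:%d", p1$chrom, p1$at,
                        length(seg), tgt$chrom, tgt$at))
    }
  }

  # tandem duplications: adjacent copy, same class
  if (config$n_tandem_duplications > 0L) {
    all_tok <- unlist(chroms)
    src <- sample_vec(all_tok, config$n_tandem_duplications)
    for (tok in src) {
      new_tok <- nrow(reg) + 1L
      reg[new_tok, ] <- list(new_tok, reg$anc_id[tok], reg$class[tok],
                             "tandem", tok)
      ci <- which(vapply(chroms, function(v) tok %in% v, logical(1)))[1L]
      at <- match(tok, chroms[[ci]])
      chroms <- insert_token(chroms, ci, at, new_tok)
      log_event("tandem_duplication", reg$anc_id[tok])
    }
  }

  # dispersed duplications: new random locus, sources drawn preferentially
  # from the duplication-prone class (exact composition at the configured
  # odds, so the simulated condition is tight); a fixed fraction of the
  # events is followed by loss of the ancestral copy
  if (config$n_dispersed_duplications > 0L) {
    all_tok <- unlist(chroms)
    nd <- config$n_dispersed_duplications
    f <- mean(reg$class[all_tok] == "prone")
    pi_prone <- config$duplication_class_odds * f /
      (config$duplication_class_odds * f + (1 - f))
    n_prone <- round(nd * pi_prone)
    prone_tok <- all_tok[reg$class[all_tok] == "prone"]
    resist_tok <- all_tok[reg$class[all_tok] == "resistant"]
    src <- c(sample_vec(prone_tok, min(n_prone, length(prone_tok))),
             sample_vec(resist_tok, min(nd - n_prone, length(resist_tok))))
    src <- sample_vec(src, length(src))   # shuffle event order
    lose <- rep(FALSE, nd)
    lose[sample.int(nd, round(config$loss_after_duplication * nd))] <- TRUE
    for (k in seq_along(src)) {
      tok <- src[k]
      new_tok <- nrow(reg) + 1L
      reg[new_tok, ] <- list(new_tok, reg$anc_id[tok], reg$class[tok],
                             "dispersed", tok)
      pos <- random_position(chroms)
      chroms <- insert_token(chroms, pos$chrom, pos$at, new_tok)
      if (lose[k]) {
        ci <- which(vapply(chroms, function(v) tok %in% v, logical(1)))[1L]
        chroms[[ci]] <- chroms[[ci]][chroms[[ci]] != tok]
        log_event("dispersed_duplication_loss", reg$anc_id[tok])
      } else {
        log_event("dispersed_duplication", reg$anc_id[tok])
      }
    }
  }

  # losses: uniform over surviving genes, with an exact per-class split so
  # losses do not perturb the class composition
  if (config$n_losses > 0L) {
    all_tok <- unlist(chroms)
    f <- mean(reg$class[all_tok] == "prone")
    n_prone <- round(config$n_losses * f)
    prone_tok <- all_tok[reg$class[all_tok] == "prone"]
    resist_tok <- all_tok[reg$class[all_tok] == "resistant"]
    gone <- c(sample_vec(prone_tok, min(n_prone, length(prone_tok))),
              sample_vec(resist_tok, min(config$n_losses - n_prone,
                                         length(resist_tok))))
    for (ci in seq_along(chroms)) {
      chroms[[ci]] <- chroms[[ci]][!chroms[[ci]] %in% gone]
    }
    for (tok in gone) log_event("loss", reg$anc_id[tok])
  }

  list(chroms = chroms, registry = reg,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(type = character(0), detail = character(0)))
}

# Lay a lineage out on chromosome sequences: random spacer, gene, spacer...
# Strand per gene is random; the genomic gene sequence is the CDS (reverse
# complemented on -). Returns a gene_set and the genome.
layout_lineage <- function(lineage, tag, anc_cds, seed, config) {
  set.seed(seed)
  reg <- lineage$registry
  genome <- character(length(lineage$chroms))
  names(genome) <- paste0("chr", seq_along(lineage$chroms))
  cds_out <- character(0)
  acc <- list(gene_id = character(0), chrom = character(0),
              strand = character(0), start = integer(0), end = integer(0),
              token = integer(0))
  for (ci in seq_along(lineage$chroms)) {
    toks <- lineage$chroms[[ci]]
    parts <- character(2L * length(toks) + 1L)
    parts[1L] <- paste(sample(c("A", "C", "G", "T"), config$spacer_len,
                              replace = TRUE), collapse = "")
    cursor <- config$spacer_len
    strands <- sample(c("+", "-"), length(toks), replace = TRUE)
    for (k in seq_along(toks)) {
      tok <- toks[k]
      cds <- anc_cds[[reg$anc_id[tok]]]
      gseq <- if (strands[k] == "+") cds else revcomp(cds)
      gid <- sprintf("%s%05d", tag, tok)
      acc$gene_id <- c(acc$gene_id, gid)
      acc$chrom <- c(acc$chrom, names(genome)[ci])
      acc$strand <- c(acc$strand, strands[k])
      acc$start <- c(acc$start, cursor + 1L)
      acc$end <- c(acc$end, cursor + nchar(gseq))
      acc$token <- c(acc$token, tok)
      cds_out[gid] <- cds
      parts[2L * k] <- gseq
      parts[2L * k + 1L] <- paste(sample(c("A", "C", "G", "T"),
                                         config$spacer_len, replace = TRUE),
                                  collapse = "")
      cursor <- cursor + nchar(gseq) + config$spacer_len
    }
    genome[ci] <- paste(parts, collapse = "")
  }
  genes <- as.data.frame(acc, stringsAsFactors = FALSE)
  gs <- gene_set(tag, genes[c("gene_id", "chrom", "strand", "start", "end")],
                 cds = cds_out, chrom_order = names(genome))
  token_of <- stats::setNames(genes$token, genes$gene_id)
  list(gene_set = gs, genome = genome, token_of = token_of)
}

#' Generate a synthetic genome pair with ground truth
#'
#' Splits an ancestral gene order into two lineages, applies the configured
#' duplications, losses and rearrangements to each, lays both out on
#' chromosome sequences, and emits homolog anchor pairs (all pairs sharing
#' an ancestral gene, duplicates included) plus a full truth record:
#' per-gene class and origin, the event log, ground-truth syntenic blocks
#' and the implied per-gene syntenic status.
#'
#' @param config a [sim_config].
#' @return list with `gene_set_a`, `gene_set_b`, `genome_a`, `genome_b`
#'   (named chromosome sequences), `anchors`, and `truth` (list with
#'   `genes_a`, `genes_b`, `blocks`, `events`).
#' @export
generate_genome_pair <- function(config = sim_config()) {
  n <- config$n_chromosomes * config$genes_per_chromosome
  set.seed(stage_seed(config$seed, 1L))
  n_prone <- round(n * config$fraction_duplication_prone)
  class <- rep("resistant", n)
  class[sample.int(n, n_prone)] <- "prone"
  ancestor <- data.frame(
    anc_id = sprintf("anc%05d", seq_len(n)),
    class = class,
    stringsAsFactors = FALSE)

  set.seed(stage_seed(config$seed, 2L))
  anc_cds <- stats::setNames(as.list(rep("", n)), ancestor$anc_id)
  for (i in seq_len(n)) {
    anc_cds[[i]] <- generate_cds(ancestor$class[i], config, n = 1L)
  }

  plan <- plan_rearrangements(config, stage_seed(config$seed, 11L))
  lin_a <- evolve_lineage(ancestor, config, stage_seed(config$seed, 3L),
                          plan$A)
  lin_b <- evolve_lineage(ancestor, config, stage_seed(config$seed, 4L),
                          plan$B)
  lay_a <- layout_lineage(lin_a, "A", anc_cds, stage_seed(config$seed, 5L),
                          config)
  lay_b <- layout_lineage(lin_b, "B", anc_cds, stage_seed(config$seed, 6L),
                          config)

  reg_a <- lin_a$registry; reg_b <- lin_b$registry
  genes_a <- lay_a$gene_set$genes; genes_b <- lay_b$gene_set$genes
  tok_a <- lay_a$token_of[genes_a$gene_id]
  tok_b <- lay_b$token_of[genes_b$gene_id]

  # anchors: every homologous pair (same ancestral gene), duplicates
  # included
  tab_a <- data.frame(gene_a = genes_a$gene_id,
                      anc_id = reg_a$anc_id[tok_a],
                      stringsAsFactors = FALSE)
  tab_b <- data.frame(gene_b = genes_b$gene_id,
                      anc_id = reg_b$anc_id[tok_b],
                      stringsAsFactors = FALSE)
  anchors <- merge(tab_a, tab_b, by = "anc_id")[c("gene_a", "gene_b")]
  anchors$score <- 100
  anchors <- anchors[order(anchors$gene_a, anchors$gene_b), , drop = FALSE]
  rownames(anchors) <- NULL

  # primary pairs: the ancestral-origin copy surviving in both lineages
  prim_a <- genes_a[reg_a$origin[tok_a] == "ancestral", , drop = FALSE]
  prim_b <- genes_b[reg_b$origin[tok_b] == "ancestral", , drop = FALSE]
  prim_a$anc_id <- reg_a$anc_id[lay_a$token_of[prim_a$gene_id]]
  prim_b$anc_id <- reg_b$anc_id[lay_b$token_of[prim_b$gene_id]]
  pp <- merge(prim_a[c("gene_id", "anc_id", "chrom", "ordinal")],
              prim_b[c("gene_id", "anc_id", "chrom", "ordinal")],
              by = "anc_id", suffixes = c("_a", "_b"))
  pp <- pp[order(pp$chrom_a, pp$ordinal_a), , drop = FALSE]

  # maximal direction-consistent runs of primary pairs
  blocks <- list()
  in_block_a <- character(0); in_block_b <- character(0)
  if (nrow(pp) > 0L) {
    run <- 1L; dir <- 0L; run_rows <- 1L
    flush <- function(rows) {
      if (length(rows) >= config$min_block) {
        blk <- pp[rows, , drop = FALSE]
        blocks[[length(blocks) + 1L]] <<- data.frame(
          chrom_a = blk$chrom_a[1L], chrom_b = blk$chrom_b[1L],
          orientation = if (blk$ordinal_b[nrow(blk)] >= blk$ordinal_b[1L])
            "+" else "-",
          n_pairs = nrow(blk),
          a_start = min(blk$ordinal_a), a_end = max(blk$ordinal_a),
          b_start = min(blk$ordinal_b), b_end = max(blk$ordinal_b),
          stringsAsFactors = FALSE)
        in_block_a <<- c(in_block_a, blk$gene_id_a)
        in_block_b <<- c(in_block_b, blk$gene_id_b)
      }
    }
    for (i in seq_len(nrow(pp))[-1L]) {
      prev <- run_rows[length(run_rows)]
      da <- pp$ordinal_a[i] - pp$ordinal_a[prev]
      db <- pp$ordinal_b[i] - pp$ordinal_b[prev]
      same_chrom <- pp$chrom_a[i] == pp$chrom_a[prev] &&
        pp$chrom_b[i] == pp$chrom_b[prev]
      ok <- same_chrom && da > 0L && da <= config$max_gap &&
        db != 0L && abs(db) <= config$max_gap &&
        (dir == 0L || sign(db) == dir)
      if (ok) {
        if (dir == 0L) dir <- sign(db)
        run_rows <- c(run_rows, i)
      } else {
        flush(run_rows)
        run_rows <- i; dir <- 0L
      }
    }
    flush(run_rows)
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks)
            else data.frame(chrom_a = character(0), chrom_b = character(0),
                            orientation = character(0), n_pairs = integer(0),
                            a_start = integer(0), a_end = integer(0),
                            b_start = integer(0), b_end = integer(0))

  # per-gene truth: block members are truly syntenic; tandem copies
  # inherit the status of their (ultimate) ancestral-copy source
  truth_gene_table <- function(genes, reg, token_of, in_block) {
    toks <- token_of[genes$gene_id]
    source_chain <- function(tok) {
      while (reg$origin[tok] == "tandem") tok <- reg$source_token[tok]
      tok
    }
    base_tok <- vapply(toks, source_chain, integer(1))
    id_of_token <- stats::setNames(names(token_of), token_of)
    base_id <- id_of_token[as.character(base_tok)]
    syntenic <- !is.na(base_id) & base_id %in% in_block
    data.frame(gene_id = genes$gene_id,
               chrom = genes$chrom, ordinal = genes$ordinal,
               anc_id = reg$anc_id[toks],
               class = reg$class[toks],
               origin = reg$origin[toks],
               true_syntenic = unname(syntenic),
               stringsAsFactors = FALSE)
  }
  truth_a <- truth_gene_table(genes_a, reg_a, lay_a$token_of, in_block_a)
  truth_b <- truth_gene_table(genes_b, reg_b, lay_b$token_of, in_block_b)

  tag_events <- function(tag, ev) {
    if (nrow(ev) == 0L) {
      return(data.frame(lineage = character(0), type = character(0),
                        detail = character(0), stringsAsFactors = FALSE))
    }
    cbind(lineage = tag, ev, stringsAsFactors = FALSE)
  }
  events <- rbind(tag_events("A", lin_a$events), tag_events("B", lin_b$events))

  list(gene_set_a = lay_a$gene_set, gene_set_b = lay_b$gene_set,
       genome_a = lay_a$genome, genome_b = lay_b$genome,
       anchors = anchors,
       truth = list(genes_a = truth_a, genes_b = truth_b,
                    blocks = blocks, events = events))
}

#' Simulate bisulfite methylation calls for one genome
#'
#' For every cytosine (both strands) inside each gene's 5' region, a
#' read-level call: the gene's true methylation level per context is drawn
#' from the class Beta distribution, and methylated read counts are
#' Binomial(read depth, level). Contexts are taken from the simulated
#' genome sequence.
#'
#' @param geneset the lineage's [gene_set].
#' @param genome the lineage's chromosome sequences.
#' @param truth_genes the per-gene truth table (supplies the class).
#' @param config a [sim_config].
#' @param seed substream seed; defaults to a stage derived from
#'   `config$seed`.
#' @param region_len 5' window length.
#' @return list with `calls` (allc-style data.frame, `context3` holding
#'   the trinucleotide string) and `true_levels` (per gene and context).
#' @export
simulate_bisulfite_calls <- function(geneset, genome, truth_genes,
                                     config = sim_config(),
                                     seed = stage_seed(config$seed, 7L),
                                     region_len = 150L) {
  set.seed(seed)
  genes <- geneset$genes
  regions <- gene_5prime_regions(genes, region_len)
  cls <- truth_genes$class[match(genes$gene_id, truth_genes$gene_id)]
  contexts <- c("CG", "CHG", "CHH")
  calls <- list()
  true_lv <- matrix(NA_real_, nrow(genes), 3L,
                    dimnames = list(genes$gene_id, contexts))
  for (i in seq_len(nrow(genes))) {
    chr <- regions$chrom[i]
    seqc <- genome[[chr]]
    lo <- regions$start[i]; hi <- min(regions$end[i], nchar(seqc))
    bases <- strsplit(substr(seqc, lo, hi), "", fixed = TRUE)[[1L]]
    pos_c <- lo + which(bases == "C") - 1L
    pos_g <- lo + which(bases == "G") - 1L
    pos <- c(pos_c, pos_g)
    strand <- c(rep("+", length(pos_c)), rep("-", length(pos_g)))
    if (length(pos) == 0L) next
    tri <- character(length(pos))
    plus <- strand == "+"
    tri[plus] <- substr(rep(seqc, sum(plus)), pos[plus], pos[plus] + 2L)
    if (any(!plus)) {
      tri[!plus] <- vapply(pos[!plus], function(p)
        revcomp(substr(seqc, max(1L, p - 2L), p)), character(1))
    }
    ctx <- collapse_context(tri)
    keep <- !is.na(ctx)
    if (!any(keep)) next
    pos <- pos[keep]; strand <- strand[keep]; tri <- tri[keep]
    ctx <- ctx[keep]
    pars <- config$meth_beta[[cls[i]]]
    lv <- vapply(contexts, function(cx)
      stats::rbeta(1L, pars[[cx]][1L], pars[[cx]][2L]), numeric(1))
    true_lv[i, ] <- lv
    depth <- config$read_depth
    m <- stats::rbinom(length(pos), depth, lv[ctx])
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = chr, pos = pos, strand = strand, context3 = tri,
      m_reads = m, total_reads = depth, stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls)
           else data.frame(chrom = character(0), pos = integer(0),
                           strand = character(0), context3 = character(0),
                           m_reads = integer(0), total_reads = integer(0))
  calls <- calls[order(calls$chrom, calls$pos, calls$strand), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls,
       true_levels = data.frame(gene_id = genes$gene_id,
                                true_mCG = true_lv[, "CG"],
                                true_mCHG = true_lv[, "CHG"],
                                true_mCHH = true_lv[, "CHH"],
                                stringsAsFactors = FALSE))
}

#' Simulate a gene-to-GO-term annotation
#'
#' Assigns synthetic GO terms with class-dependent propensities: a third of
#' the terms are biased toward the duplication-prone class (defense-like),
#' a third toward the resistant class (housekeeping-like), a third neutral,
#' so enrichment by synteny class is detectable by construction.
#'
#' @param truth_genes per-gene truth table of one lineage.
#' @param config a [sim_config].
#' @param seed substream seed.
#' @param n_terms_per_group terms per bias group.
#' @param p_biased,p_background annotation probability for the favored
#'   class / for everything else.
#' @return data.frame with `gene_id`, `go_term`.
#' @export
simulate_go_map <- function(truth_genes, config = sim_config(),
                            seed = stage_seed(config$seed, 9L),
                            n_terms_per_group = 10L,
                            p_biased = 0.18, p_background = 0.04) {
  set.seed(seed)
  groups <- rep(c("prone", "resistant", "neutral"), each = n_terms_per_group)
  terms <- sprintf("GO:%07d", seq_along(groups))
  rows <- list()
  for (t in seq_along(terms)) {
    p <- switch(groups[t],
                prone = ifelse(truth_genes$class == "prone",
                               p_biased, p_background),
                resistant = ifelse(truth_genes$class == "resistant",
                                   p_biased, p_background),
                neutral = rep(p_background * 2, nrow(truth_genes)))
    hit <- stats::runif(nrow(truth_genes)) < p
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = truth_genes$gene_id[hit], go_term = terms[t],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$go_term), , drop = FALSE]
}

# ---- fixture writing -------------------------------------------------------

write_gff3 <- function(geneset, path) {
  g <- geneset$genes
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines,
      sprintf("%s\tsyngc\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], gid),
      sprintf("%s\tsyngc\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], gid, gid),
      sprintf("%s\tsyngc\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds;Parent=%s.1",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], gid, gid))
  }
  writeLines(lines, path)
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80L)
}

#' Write a complete synthetic input fixture
#'
#' Runs the generator and writes every input the pipeline reads — genome
#' FASTA, gene-model GFF3, CDS FASTA (keyed by mRNA id), anchor TSV,
#' allc-style methylation TSV and GO map per lineage — plus the truth
#' tables, into `dir`.
#'
#' @param config a [sim_config].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly; also returns the
#'   in-memory simulation under `$sim`.
#' @export
simulate_fixture <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genome_pair(config)
  bs_a <- simulate_bisulfite_calls(sim$gene_set_a, sim$genome_a,
                                   sim$truth$genes_a, config,
                                   seed = stage_seed(config$seed, 7L))
  bs_b <- simulate_bisulfite_calls(sim$gene_set_b, sim$genome_b,
                                   sim$truth$genes_b, config,
                                   seed = stage_seed(config$seed, 8L))
  go_a <- simulate_go_map(sim$truth$genes_a, config,
                          seed = stage_seed(config$seed, 9L))
  go_b <- simulate_go_map(sim$truth$genes_b, config,
                          seed = stage_seed(config$seed, 10L))

  p <- function(f) file.path(dir, f)
  paths <- list(
    genome_a = p("genome_A.fa"), genome_b = p("genome_B.fa"),
    gff3_a = p("genes_A.gff3"), gff3_b = p("genes_B.gff3"),
    cds_a = p("cds_A.fa"), cds_b = p("cds_B.fa"),
    anchors = p("anchors_A_B.tsv"),
    allc_a = p("allc_A.tsv"), allc_b = p("allc_B.tsv"),
    go_a = p("go_A.tsv"), go_b = p("go_B.tsv"),
    truth_genes_a = p("truth_genes_A.tsv"),
    truth_genes_b = p("truth_genes_B.tsv"),
    truth_blocks = p("truth_blocks.tsv"),
    truth_events = p("truth_events.tsv"),
    true_levels_a = p("truth_methylation_A.tsv"),
    true_levels_b = p("truth_methylation_B.tsv"))

  write_fasta(sim$genome_a, paths$genome_a)
  write_fasta(sim$genome_b, paths$genome_b)
  write_gff3(sim$gene_set_a, paths$gff3_a)
  write_gff3(sim$gene_set_b, paths$gff3_b)
  # CDS FASTA keyed by mRNA id (first splice variant)
  cds_a <- sim$gene_set_a$cds
  names(cds_a) <- paste0(names(cds_a), ".1")
  cds_b <- sim$gene_set_b$cds
  names(cds_b) <- paste0(names(cds_b), ".1")
  write_fasta(cds_a, paths$cds_a)
  write_fasta(cds_b, paths$cds_b)
  tsv <- function(df, path, col.names = TRUE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  }
  tsv(sim$anchors, paths$anchors, col.names = FALSE)
  tsv(bs_a$calls, paths$allc_a, col.names = FALSE)
  tsv(bs_b$calls, paths$allc_b, col.names = FALSE)
  tsv(go_a, paths$go_a)
  tsv(go_b, paths$go_b)
  tsv(sim$truth$genes_a, paths$truth_genes_a)
  tsv(sim$truth$genes_b, paths$truth_genes_b)
  tsv(sim$truth$blocks, paths$truth_blocks)
  tsv(sim$truth$events, paths$truth_events)
  tsv(bs_a$true_levels, paths$true_levels_a)
  tsv(bs_b$true_levels, paths$true_levels_b)
  out <- c(paths, list(sim = sim))
  invisible(out)
}
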
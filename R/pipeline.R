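#' Pipeline configuration
#'
#' Declares the per-species input files and the genome comparisons to run.
#'
#' @param species named list; each element a list with paths `gff3`, `cds`
#'   and optionally `genome` (assembly FASTA, enables copy-number and
#'   context checks), `allc` (methylation calls) and `go` (gene-to-GO TSV
#'   with header `gene_id`, `go_term`).
#' @param comparisons list of two-element character vectors of species
#'   tags; self-comparisons are allowed (the identity diagonal is dropped
#'   before chaining).
#' @param chain [chain_params] used for every comparison.
#' @param region_len 5' methylation window (bp).
#' @param copy_query_len length of the copy-number query (bp).
#' @param seed recorded in output headers (the pipeline itself is
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(species, comparisons, chain = chain_params(),
                            region_len = 150L, copy_query_len = 150L,
                            seed = 0L) {
  if (length(species) == 0L || is.null(names(species))) {
    stop("at least one named species entry required")
  }
  if (length(comparisons) == 0L) stop("at least one comparison required")
  for (cmp in comparisons) {
    if (!all(cmp %in% names(species))) {
      stop("comparison references undeclared species: ",
           paste(cmp, collapse = " vs "))
    }
  }
  for (tag in names(species)) {
    for (f in c("gff3", "cds", "genome", "allc", "go", "anchors")) {
      path <- species[[tag]][[f]]
      if (!is.null(path) && f != "anchors" && !file.exists(path)) {
        stop(sprintf("species %s: missing input file %s (%s)", tag, f, path))
      }
    }
  }
  structure(list(species = species, comparisons = comparisons,
                 chain = chain, region_len = as.integer(region_len),
                 copy_query_len = as.integer(copy_query_len),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Pipeline configuration for a simulated fixture directory
#'
#' Builds a two-species [pipeline_config] pointing at the files written by
#' [simulate_fixture].
#'
#' @param dir fixture directory.
#' @param chain [chain_params] for the A-vs-B comparison.
#' @inheritParams pipeline_config
#' @return a `pipeline_config`.
#' @export
fixture_pipeline_config <- function(dir, chain = chain_params(),
                                    region_len = 150L, seed = 0L) {
  p <- function(f) file.path(dir, f)
  pipeline_config(
    species = list(
      A = list(gff3 = p("genes_A.gff3"), cds = p("cds_A.fa"),
               genome = p("genome_A.fa"), allc = p("allc_A.tsv"),
               go = p("go_A.tsv"),
               anchors = list(B = p("anchors_A_B.tsv"))),
      B = list(gff3 = p("genes_B.gff3"), cds = p("cds_B.fa"),
               genome = p("genome_B.fa"), allc = p("allc_B.tsv"),
               go = p("go_B.tsv"))),
    comparisons = list(stats::setNames(c("A", "B"), NULL)),
    chain = chain, region_len = region_len, seed = seed)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — input parsing, tandem
#' collapsing and anchor chaining per comparison, synteny classification,
#' CDS filters and GC3 metrics, 5'-end copy number, weighted methylation,
#' and the association statistics — and writes one TSV bundle under
#' `out_dir`. Outputs carry a header comment with package version, a
#' configuration hash and the seed; a rerun on identical inputs is
#' byte-identical.
#'
#' @param config a [pipeline_config]. Anchor files are given per
#'   comparison as `config$species[[a]]$anchors[[b]]` or, more simply, via
#'   the `anchors` argument.
#' @param out_dir output directory (created if needed).
#' @param anchors optional named list of anchor-file paths or anchor
#'   data.frames keyed `"A_vs_B"`; unnamed single-comparison lists are
#'   matched positionally.
#' @return invisibly, a list with the per-species gene-metrics tables,
#'   per-comparison blocks, synteny statuses and the statistics tables.
#' @export
run_pipeline <- function(config, out_dir, anchors = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("syngc %s | config %s | seed %d",
                 as.character(utils::packageVersion("syngc")),
                 config_hash(config), config$seed)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
    message(sprintf(fmt, ...))
  }

  tags <- names(config$species)
  gene_sets <- list(); genomes <- list()
  for (tag in tags) {
    sp <- config$species[[tag]]
    gene_sets[[tag]] <- read_gene_models(sp$gff3, sp$cds, tag)
    say("[io] %s: %d genes, %d with CDS", tag,
        nrow(gene_sets[[tag]]$genes), length(gene_sets[[tag]]$cds))
    if (!is.null(sp$genome)) {
      genomes[[tag]] <- prepare_genome(
        Biostrings::readDNAStringSet(sp$genome))
    }
  }

  cmp_tag <- vapply(config$comparisons, paste, character(1), collapse = "_vs_")
  detections <- list()
  memberships <- stats::setNames(
    replicate(length(tags), list(), simplify = FALSE), tags)
  for (k in seq_along(config$comparisons)) {
    cmp <- config$comparisons[[k]]
    a <- cmp[1L]; b <- cmp[2L]
    anc <- NULL
    if (!is.null(anchors)) {
      anc <- if (!is.null(names(anchors)) && cmp_tag[k] %in% names(anchors))
        anchors[[cmp_tag[k]]] else anchors[[k]]
    }
    if (is.null(anc)) anc <- config$species[[a]]$anchors[[b]]
    if (is.null(anc)) stop("no anchors supplied for comparison ", cmp_tag[k])
    if (is.character(anc)) {
      anc <- read_anchor_pairs(anc, gene_sets[[a]], gene_sets[[b]])
    }
    det <- detect_synteny(anc, gene_sets[[a]], gene_sets[[b]], config$chain)
    validate_blocks(det$blocks, config$chain)
    detections[[cmp_tag[k]]] <- det
    memberships[[a]][[cmp_tag[k]]] <- det$members_a
    memberships[[b]][[cmp_tag[k]]] <- det$members_b
    say("[synteny] %s: %d blocks, %d anchors in blocks", cmp_tag[k],
        nrow(det$blocks$blocks), nrow(det$blocks$anchors))
  }

  metrics <- list(); statuses <- list()
  stats_rows <- list(); meth_class_rows <- list(); corr_rows <- list()
  dist_rows <- list(); curve_rows <- list(); enrich_rows <- list()
  meth_tables <- list()
  for (tag in tags) {
    gs <- gene_sets[[tag]]
    status <- classify_synteny(gs, memberships[[tag]])
    statuses[[tag]] <- status
    gc <- gene_gc_table(gs)
    say("[gc] %s: %d/%d genes pass CDS filters", tag,
        sum(gc$filter_status == "pass"), nrow(gc))
    cn <- if (tag %in% names(genomes)) {
      gene_copy_table(gs, genomes[[tag]], query_len = config$copy_query_len)
    } else {
      data.frame(gene_id = gs$genes$gene_id, n_hits = NA_integer_,
                 copy_class = NA_character_, stringsAsFactors = FALSE)
    }
    meth <- if (!is.null(config$species[[tag]]$allc)) {
      calls <- read_methylation_calls(config$species[[tag]]$allc)
      gene_methylation_table(gs, calls, config$region_len)
    } else {
      data.frame(gene_id = gs$genes$gene_id, mCG = NA_real_,
                 mCHG = NA_real_, mCHH = NA_real_,
                 n_sites_CG = 0L, n_sites_CHG = 0L, n_sites_CHH = 0L,
                 n_reads_CG = 0, n_reads_CHG = 0, n_reads_CHH = 0,
                 stringsAsFactors = FALSE)
    }
    meth_tables[[tag]] <- meth

    tab <- data.frame(
      gene_id = gs$genes$gene_id, species = tag, chrom = gs$genes$chrom,
      ordinal = gs$genes$ordinal,
      syntenic = as.integer(status$syntenic),
      gc3_50 = gc$gc3_50, gc3_full = gc$gc3_full,
      copy_class = cn$copy_class,
      mCG = meth$mCG, mCHG = meth$mCHG, mCHH = meth$mCHH,
      filter_status = gc$filter_status, stringsAsFactors = FALSE)
    metrics[[tag]] <- tab

    # synteny vs GC3-50
    pass <- tab$filter_status == "pass"
    x <- tab$gc3_50[pass & tab$syntenic == 1L]
    y <- tab$gc3_50[pass & tab$syntenic == 0L]
    if (length(x) > 0L && length(y) > 0L) {
      wt <- wilcoxon_rank_sum(x, y)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        species = tag, grouping = "synteny",
        group_x = "syntenic", group_y = "non_syntenic",
        n_x = length(x), n_y = length(y),
        mean_x = mean(x), mean_y = mean(y),
        median_x = stats::median(x), median_y = stats::median(y),
        mean_diff = mean(x) - mean(y),
        statistic = wt$statistic, p_value = wt$p_value,
        stringsAsFactors = FALSE)
    }
    # single vs multicopy GC3-50
    x <- tab$gc3_50[pass & !is.na(tab$copy_class) & tab$copy_class == "single"]
    y <- tab$gc3_50[pass & !is.na(tab$copy_class) & tab$copy_class != "single"]
    if (length(x) > 0L && length(y) > 0L) {
      wt <- wilcoxon_rank_sum(x, y)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        species = tag, grouping = "copy_number",
        group_x = "single", group_y = "multicopy",
        n_x = length(x), n_y = length(y),
        mean_x = mean(x), mean_y = mean(y),
        median_x = stats::median(x), median_y = stats::median(y),
        mean_diff = mean(x) - mean(y),
        statistic = wt$statistic, p_value = wt$p_value,
        stringsAsFactors = FALSE)
    }

    # class methylation summaries
    if (any(!is.na(meth$mCG))) {
      syn_lab <- ifelse(status$syntenic, "syntenic", "non_syntenic")
      mc <- aggregate_methylation_by_class(meth, syn_lab)
      mc <- cbind(species = tag, grouping = "synteny", mc,
                  stringsAsFactors = FALSE)
      meth_class_rows[[length(meth_class_rows) + 1L]] <- mc
      if (any(!is.na(cn$copy_class))) {
        mc2 <- aggregate_methylation_by_class(meth, cn$copy_class)
        mc2 <- cbind(species = tag, grouping = "copy_number", mc2,
                     stringsAsFactors = FALSE)
        meth_class_rows[[length(meth_class_rows) + 1L]] <- mc2
      }
      # methylation ~ GC3-50 correlations
      for (ctx in c("CG", "CHG", "CHH")) {
        v <- meth[[paste0("m", ctx)]]
        ok <- pass & !is.na(v)
        if (sum(ok) >= 3L) {
          co <- correlate(tab$gc3_50[ok], v[ok])
          corr_rows[[length(corr_rows) + 1L]] <- cbind(
            species = tag, context = ctx, co, stringsAsFactors = FALSE)
        }
      }
      # binned curves
      for (ctx in c("CG", "CHG", "CHH")) {
        bc <- methylation_by_gc3_bins(meth[pass, , drop = FALSE],
                                      stats::setNames(tab$gc3_50[pass],
                                                      tab$gene_id[pass]),
                                      context = ctx)
        curve_rows[[length(curve_rows) + 1L]] <- cbind(
          species = tag, context = ctx, bc, stringsAsFactors = FALSE)
      }
    }

    # GC3-50 histograms by synteny class
    dist <- gc3_50_distribution(tab$gc3_50[pass],
                                ifelse(tab$syntenic[pass] == 1L,
                                       "syntenic", "non_syntenic"))
    dist_rows[[length(dist_rows) + 1L]] <- cbind(species = tag, dist,
                                                 stringsAsFactors = FALSE)

    # GO enrichment
    if (!is.null(config$species[[tag]]$go)) {
      go_map <- utils::read.delim(config$species[[tag]]$go,
                                  stringsAsFactors = FALSE)
      enr <- go_enrichment(go_map, status, species = tag)
      enrich_rows[[length(enrich_rows) + 1L]] <- enr
    }
  }

  # ---- write bundle ----
  w <- function(df, file) {
    con <- file(file.path(out_dir, file), open = "wt")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  for (tag in tags) {
    write_gene_table(metrics[[tag]],
                     file.path(out_dir, sprintf("gene_metrics_%s.tsv", tag)),
                     header_comment = hdr)
  }
  all_blocks <- do.call(rbind, lapply(names(detections), function(ct)
    cbind(comparison = ct, detections[[ct]]$blocks$blocks,
          stringsAsFactors = FALSE)))
  all_anchors <- do.call(rbind, lapply(names(detections), function(ct)
    cbind(comparison = ct, detections[[ct]]$blocks$anchors,
          stringsAsFactors = FALSE)))
  w(all_blocks, "blocks.tsv")
  w(all_anchors, "block_anchors.tsv")
  bind_or_empty <- function(rows) {
    if (length(rows)) do.call(rbind, rows) else data.frame()
  }
  w(bind_or_empty(stats_rows), "comparison_stats.tsv")
  w(bind_or_empty(meth_class_rows), "methylation_by_class.tsv")
  w(bind_or_empty(corr_rows), "correlations.tsv")
  w(bind_or_empty(dist_rows), "gc3_distribution.tsv")
  w(bind_or_empty(curve_rows), "binned_curves.tsv")
  if (length(enrich_rows)) {
    enr_all <- do.call(rbind, enrich_rows)
    w(enr_all, "go_enrichment.tsv")
    w(cross_species_enrichment(enr_all), "go_cross_species.tsv")
  }
  writeLines(c(paste0("# ", hdr), log_lines),
             file.path(out_dir, "run_log.txt"))

  invisible(list(
    gene_sets = gene_sets, statuses = statuses, metrics = metrics,
    methylation = meth_tables, detections = detections,
    stats = list(comparisons = bind_or_empty(stats_rows),
                 methylation_by_class = bind_or_empty(meth_class_rows),
                 correlations = bind_or_empty(corr_rows),
                 gc3_distribution = bind_or_empty(dist_rows),
                 binned_curves = bind_or_empty(curve_rows),
                 enrichment = bind_or_empty(enrich_rows))))
}
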
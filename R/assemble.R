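#' Assemble transcripts from spliced alignments
#'
#' Runs the full pipeline: alignment ingestion, region detection, per-region
#' exon inference by the subexon-coverage linear program, splice-graph
#' construction, maximal-path enumeration, and transcript selection by
#' greedy set cover over read/pair contiguity constraints. With an
#' annotation and `weighted = TRUE`, candidate transcripts whose consecutive
#' intron pairs are absent from the annotation are up-weighted (penalised)
#' in the weighted set cover.
#'
#' @param sam Path to a SAM file of spliced alignments.
#' @param annotation Optional GTF path supplying intron-pair evidence for
#'   the weighted selection mode.
#' @param weighted Use annotation-weighted selection (default: when an
#'   annotation is given).
#' @param min_mapq,max_gap,min_region_len,min_junction_support,min_anchor
#'   Ingestion and region/junction filters (see [read_alignments()],
#'   [detect_regions()], [extract_splice_sites()]).
#' @param frag_len,frag_sd Optional fragment-length override; required for
#'   libraries where estimation is impossible (e.g. single-end with the
#'   pair checks desired). When `NULL` and pairs are present, statistics
#'   are estimated from intra-region unspliced pairs.
#' @param lambda Weight scale for the weighted mode.
#' @param lp_lower_bound Minimum subexon coverage in the LP.
#' @param cap_candidates,cap_sites Per-region enumeration caps.
#' @param max_paths Per-component cap on candidate transcripts.
#' @return An object of class `isocover_fit`. Its `transcripts` element is
#'   a tibble ready for [write_gtf()]; see also [tidy.isocover_fit()] and
#'   [glance.isocover_fit()].
#' @export
assemble_transcripts <- function(sam, annotation = NULL,
                                 weighted = !is.null(annotation),
                                 min_mapq = 0, max_gap = 0,
                                 min_region_len = 25,
                                 min_junction_support = 1, min_anchor = 8,
                                 frag_len = NULL, frag_sd = NULL,
                                 lambda = 1, lp_lower_bound = 1,
                                 cap_candidates = 16, cap_sites = 12,
                                 max_paths = 1000) {
  cfg <- list(min_mapq = min_mapq, max_gap = max_gap,
              min_region_len = min_region_len,
              min_junction_support = min_junction_support,
              min_anchor = min_anchor, frag_len = frag_len,
              frag_sd = frag_sd, lambda = lambda,
              lp_lower_bound = lp_lower_bound,
              cap_candidates = cap_candidates, cap_sites = cap_sites,
              max_paths = max_paths, weighted = weighted)

  aln <- read_alignments(sam, min_mapq = min_mapq)
  regions <- detect_regions(aln, max_gap = max_gap,
                            min_region_len = min_region_len)
  stats <- NULL
  if (!is.null(frag_len)) {
    stats <- estimate_fragment_stats(aln$pairs,
                                     override = c(frag_len,
                                                  frag_sd %||% 0))
  } else if (nrow(aln$pairs) > 0L) {
    stats <- tryCatch(
      estimate_fragment_stats(aln$pairs, regions = regions),
      error = function(e) NULL)
  }

  # per-region exon inference; intervals are numbered globally in region
  # order so interval_id equals the row index of the pooled table
  interval_rows <- list()
  exon_rows <- list()
  offset <- 0L
  for (ri in seq_len(nrow(regions))) {
    region <- regions[ri, ]
    sites <- extract_splice_sites(aln$junctions, region,
                                  min_support = min_junction_support,
                                  min_anchor = min_anchor)
    iv <- partition_intervals(region, unique(sites$pos), aln$reads)
    sel <- select_exon_set(region, iv, sites, aln$reads, aln$pairs,
                           aln$junctions, stats,
                           config = list(lp_lower_bound = lp_lower_bound,
                                         cap_candidates = cap_candidates,
                                         cap_sites = cap_sites))
    iv$interval_id <- offset + iv$iv
    iv$region_id <- region$region_id
    iv$contig <- region$contig
    interval_rows[[ri]] <- iv
    ex <- sel$exons
    ex$first_iv <- ex$first_iv + offset
    ex$last_iv <- ex$last_iv + offset
    exon_rows[[ri]] <- ex
    offset <- offset + nrow(iv)
  }
  intervals <- dplyr::bind_rows(interval_rows)
  exons <- dplyr::bind_rows(exon_rows)
  if (nrow(intervals) > 0L) {
    intervals <- dplyr::select(intervals, "interval_id", "region_id",
                               "contig", "start", "end", "len", "cbar")
  }

  if (nrow(exons) == 0L) {
    return(new_isocover_fit(empty_transcripts(), exons, intervals, regions,
                            aln, stats, cfg,
                            candidates = empty_transcripts(),
                            n_constraints = 0L, n_pruned = 0L,
                            selected = integer(0)))
  }

  graph <- build_splice_graph(exons, aln$junctions,
                              min_support = min_junction_support,
                              min_anchor = min_anchor)
  cands <- enumerate_maximal_paths(graph, max_paths = max_paths)
  constraints <- derive_constraints(aln, intervals)
  cgraph <- build_constraint_graph(cands, constraints, intervals, stats)
  pruned <- prune_unsatisfiable(cgraph)

  if (weighted) {
    if (is.null(annotation)) {
      stop("weighted selection requires an annotation GTF")
    }
    evidence <- load_evidence_intron_pairs(annotation)
    cw <- transcript_weights(cands, evidence, lambda = lambda)
    w <- stats::setNames(cw$weight, cw$transcript_id)
    selected <- weighted_greedy_set_cover(pruned, w)
  } else {
    selected <- greedy_set_cover(pruned)
  }

  chosen <- cands[match(sort(selected), cands$transcript_id), ]
  transcripts <- finalize_transcripts(chosen)
  new_isocover_fit(transcripts, exons, intervals, regions, aln, stats, cfg,
                   candidates = cands,
                   n_constraints = nrow(constraints),
                   n_pruned = attr(pruned, "n_removed"),
                   selected = selected)
}

empty_transcripts <- function() {
  tibble::tibble(transcript_id = character(), gene_id = character(),
                 contig = character(), strand = character(),
                 exons = list(), introns = list(), n_exons = integer())
}

# stable public ids: genes numbered by genomic position of their leftmost
# selected transcript, transcripts numbered within the gene
finalize_transcripts <- function(chosen) {
  if (nrow(chosen) == 0L) return(empty_transcripts())
  chosen$t_start <- purrr::map_dbl(chosen$exons, ~ .x[1L, 1L])
  chosen <- dplyr::arrange(chosen, .data$contig, .data$t_start,
                           purrr::map_chr(chosen$nodes, paste,
                                          collapse = ","))
  gene_order <- chosen |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(contig = dplyr::first(.data$contig),
                     s = min(.data$t_start), .groups = "drop") |>
    dplyr::arrange(.data$contig, .data$s)
  gmap <- stats::setNames(sprintf("G%04d", seq_len(nrow(gene_order))),
                          gene_order$gene_id)
  chosen |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(tnum = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(gene_id = unname(gmap[as.character(.data$gene_id)]),
                  transcript_id = sprintf("%s.%d", .data$gene_id,
                                          .data$tnum)) |>
    dplyr::select("transcript_id", "gene_id", "contig", "strand", "exons",
                  "introns", "n_exons")
}

new_isocover_fit <- function(transcripts, exons, intervals, regions, aln,
                             stats, cfg, candidates, n_constraints,
                             n_pruned, selected) {
  structure(list(transcripts = transcripts, exons = exons,
                 intervals = intervals, regions = regions,
                 junctions = aln$junctions, stats = stats, config = cfg,
                 candidates = candidates, n_constraints = n_constraints,
                 n_pruned = n_pruned, selected = selected,
                 n_reads = nrow(aln$reads), n_pairs = nrow(aln$pairs),
                 n_skipped = aln$skipped),
            class = "isocover_fit")
}

#' @describeIn assemble_transcripts One row per assembled transcript
#'   (coordinates, exon count, intron-chain key).
#' @param x An `isocover_fit`.
#' @param ... Unused.
#' @export
tidy.isocover_fit <- function(x, ...) {
  tx <- x$transcripts
  tibble::tibble(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    contig = tx$contig,
    strand = tx$strand,
    start = purrr::map_dbl(tx$exons, ~ .x[1L, 1L]),
    end = purrr::map_dbl(tx$exons, ~ .x[nrow(.x), 2L]),
    n_exons = tx$n_exons,
    intron_chain = purrr::map_chr(tx$introns, chain_key))
}

#' @describeIn assemble_transcripts One-row run summary (input, region,
#'   candidate and selection counts).
#' @export
glance.isocover_fit <- function(x, ...) {
  tibble::tibble(
    n_reads = x$n_reads, n_pairs = x$n_pairs, n_skipped = x$n_skipped,
    n_regions = nrow(x$regions), n_intervals = nrow(x$intervals),
    n_exons = nrow(x$exons), n_candidates = nrow(x$candidates),
    n_constraints = x$n_constraints, n_pruned = x$n_pruned,
    n_genes = length(unique(x$transcripts$gene_id)),
    n_transcripts = nrow(x$transcripts))
}

#' @export
print.isocover_fit <- function(x, ...) {
  g <- glance(x)
  cat("isocover fit:", g$n_transcripts, "transcripts in", g$n_genes,
      "genes\n")
  cat("  reads:", g$n_reads, "(", g$n_pairs, "pairs,", g$n_skipped,
      "skipped )\n")
  cat("  regions:", g$n_regions, " exons:", g$n_exons, " candidates:",
      g$n_candidates, "\n")
  cat("  constraints:", g$n_constraints, "(", g$n_pruned,
      "unsatisfiable pruned )\n")
  invisible(x)
}

#' Plot the isoform count distribution of an assembly
#'
#' @param object An `isocover_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isocover_fit <- function(object, ...) {
  df <- dplyr::count(object$transcripts, .data$gene_id,
                     name = "isoforms")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$isoforms))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "isoforms per gene", y = "genes") +
    ggplot2::theme_minimal()
}
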
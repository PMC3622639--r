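#' Build a splice graph from chosen exons and junctions
#'
#' Exons are nodes; a directed edge connects exon `u` to exon `v` when a
#' filtered junction has its donor at `u`'s right boundary and its acceptor
#' at `v`'s left boundary, on a compatible strand. Edges always point from
#' genomic left to right, so the graph is acyclic by construction (this is
#' still asserted). Junctions whose boundaries match no exon are counted as
#' dangling.
#'
#' @param exons Exon tibble (columns `contig`, `strand`, `start`, `end`,
#'   optionally `first_iv`, `last_iv`), e.g. pooled [select_exon_set()]
#'   results.
#' @param junctions Junction tibble from [read_alignments()].
#' @param min_support,min_anchor Junction filters (same semantics as
#'   [extract_splice_sites()]).
#' @return A list of class `splice_graph`: `nodes` (with `node_id` and
#'   `gene_id` from connected components), `edges` (`from`, `to`,
#'   `support`, `strand`), `n_dangling`.
#' @export
build_splice_graph <- function(exons, junctions, min_support = 1,
                               min_anchor = 8) {
  nodes <- exons |>
    dplyr::distinct(.data$contig, .data$strand, .data$start, .data$end,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$contig, .data$start, .data$end, .data$strand) |>
    dplyr::mutate(node_id = dplyr::row_number(), .before = 1L)
  j <- junctions[junctions$support >= min_support &
                   junctions$max_anchor >= min_anchor, ]
  edges <- list()
  n_dangling <- 0L
  for (r in seq_len(nrow(j))) {
    from <- nodes$node_id[nodes$contig == j$contig[r] &
                            nodes$end == j$donor[r] &
                            strand_compatible(nodes$strand, j$strand[r])]
    to <- nodes$node_id[nodes$contig == j$contig[r] &
                          nodes$start == j$acceptor[r] &
                          strand_compatible(nodes$strand, j$strand[r])]
    if (length(from) == 0L || length(to) == 0L) {
      n_dangling <- n_dangling + 1L
      next
    }
    edges[[length(edges) + 1L]] <-
      tidyr::expand_grid(from = from, to = to) |>
      dplyr::mutate(support = j$support[r], strand = j$strand[r])
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(from = integer(), to = integer(), support = integer(),
                   strand = character())
  if (nrow(edges) > 0L &&
      any(nodes$start[edges$to] < nodes$end[edges$from])) {
    stop("internal error: splice graph edge pointing backwards")
  }
  nodes$gene_id <- graph_components(nrow(nodes), edges)
  structure(list(nodes = nodes, edges = edges, n_dangling = n_dangling),
            class = "splice_graph")
}

# connected components (undirected), labelled 1..k in order of the
# leftmost node of each component
graph_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges$from[r]); b <- find(edges$to[r])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  # path-compress into labels; components get sequential ids by first node
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Enumerate maximal paths of a splice graph as candidate transcripts
#'
#' A candidate transcript is a maximal path from a source (no incoming
#' edges) to a sink (no outgoing edges); isolated exons yield single-exon
#' candidates. When a connected component encodes more than `max_paths`
#' paths, only the `max_paths` paths of highest cumulative edge support are
#' returned (ties broken lexicographically on node ids) and the result
#' carries a `truncated` attribute.
#'
#' @param graph A `splice_graph`.
#' @param max_paths Per-component cap on enumerated paths.
#' @return A tibble of candidate transcripts: `transcript_id`, `gene_id`,
#'   `contig`, `strand`, `nodes` (list of node ids), `exons` (list of
#'   two-column matrices), `introns` (list), `n_exons`, `support`.
#' @export
enumerate_maximal_paths <- function(graph, max_paths = 1000) {
  nodes <- graph$nodes
  edges <- graph$edges
  truncated <- FALSE
  out <- list()
  for (g in sort(unique(nodes$gene_id))) {
    comp_nodes <- nodes$node_id[nodes$gene_id == g]
    comp_edges <- edges[edges$from %in% comp_nodes, ]
    paths <- component_paths(comp_nodes, comp_edges, max_paths)
    if (attr(paths, "truncated")) truncated <- TRUE
    for (p in paths) {
      ex <- nodes[match(p$path, nodes$node_id), ]
      exm <- cbind(ex$start, ex$end)
      strand <- consensus_strand(
        c(ex$strand[ex$strand != "."],
          comp_edges$strand[comp_edges$strand != "*"]) |>
          (\(x) if (length(x)) x else "*")())
      if (strand == "*") strand <- "."
      out[[length(out) + 1L]] <- tibble::tibble(
        gene_id = g, contig = ex$contig[1L], strand = strand,
        nodes = list(p$path), exons = list(exm),
        introns = list(blocks_to_introns(exm)),
        n_exons = nrow(exm), support = p$support)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(gene_id = integer(), contig = character(),
                          strand = character(), nodes = list(),
                          exons = list(), introns = list(),
                          n_exons = integer(), support = numeric())
  } else {
    res <- res |>
      dplyr::mutate(t_start = purrr::map_dbl(.data$exons, ~ .x[1L, 1L])) |>
      dplyr::arrange(.data$gene_id, .data$t_start,
                     purrr::map_chr(.data$nodes, paste, collapse = ",")) |>
      dplyr::select(-"t_start") |>
      dplyr::mutate(transcript_id = dplyr::row_number(), .before = 1L)
  }
  attr(res, "truncated") <- truncated
  res
}

# all (or the top-k by support) source->sink paths within one component
component_paths <- function(comp_nodes, comp_edges, max_paths) {
  succ <- split(seq_len(nrow(comp_edges)), comp_edges$from)
  has_in <- comp_nodes %in% comp_edges$to
  has_out <- comp_nodes %in% comp_edges$from
  sources <- comp_nodes[!has_in]
  # count paths per node (DAG ordered by genomic coordinate = node id)
  order_desc <- sort(comp_nodes, decreasing = TRUE)
  npaths <- numeric(max(comp_nodes))
  for (v in order_desc) {
    e <- succ[[as.character(v)]]
    npaths[v] <- if (is.null(e)) 1 else
      sum(npaths[comp_edges$to[e]])
  }
  total <- sum(npaths[sources])
  trunc <- total > max_paths
  # top-k suffix DP: per node, best path suffixes (support sum, path)
  k <- if (trunc) max_paths else Inf
  suffix <- vector("list", max(comp_nodes))
  for (v in order_desc) {
    e <- succ[[as.character(v)]]
    if (is.null(e)) {
      suffix[[v]] <- list(list(support = 0, path = v))
    } else {
      items <- list()
      for (ei in e) {
        to <- comp_edges$to[ei]
        w <- comp_edges$support[ei]
        for (sfx in suffix[[to]]) {
          items[[length(items) + 1L]] <-
            list(support = sfx$support + w, path = c(v, sfx$path))
        }
      }
      items <- rank_paths(items)
      if (is.finite(k) && length(items) > k) items <- items[seq_len(k)]
      suffix[[v]] <- items
    }
  }
  all_paths <- unlist(lapply(sources, function(s) suffix[[s]]),
                      recursive = FALSE)
  all_paths <- rank_paths(all_paths)
  if (is.finite(k) && length(all_paths) > k) {
    all_paths <- all_paths[seq_len(k)]
  }
  attr(all_paths, "truncated") <- trunc
  all_paths
}

# order path records by decreasing support, ties lexicographic on node ids
rank_paths <- function(items) {
  if (length(items) <= 1L) return(items)
  sup <- vapply(items, `[[`, numeric(1), "support")
  keys <- vapply(items, function(x) paste(sprintf("%09d", x$path),
                                          collapse = ","), character(1))
  items[order(-sup, keys)]
}
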
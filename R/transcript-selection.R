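#' Derive deduplicated contiguity constraints from reads and pairs
#'
#' Each read (or read pair) yields a constraint: the set of global interval
#' ids its blocks overlap, the junction chain it contains, and, for pairs,
#' the (left-start interval, right-end interval) class used for the
#' fragment-length check. Reads or pairs with identical content collapse to
#' one constraint with accumulated multiplicity. Reads overlapping no
#' interval (outside all retained regions) are ignored and counted.
#'
#' @param aln An `alignment_set` from [read_alignments()].
#' @param intervals Global interval tibble (`interval_id`, `contig`,
#'   `start`, `end`, `len`), e.g. from [assemble_transcripts()]'s
#'   intermediate state.
#' @return A tibble of class `constraint_set`: `constraint_id`, `contig`,
#'   `strand`, `mates` (list; each mate holds `ivs` and `juncs`),
#'   `pair_iv` (list, `c(i, j)` or `NULL`), `multiplicity`. The number of
#'   ignored reads is attached as attribute `n_ignored`.
#' @export
derive_constraints <- function(aln, intervals) {
  reads <- aln$reads
  pairs <- aln$pairs
  paired_ids <- unique(pairs$read_id)
  singles <- reads[!(reads$is_paired & reads$read_id %in% paired_ids), ]

  iv_index <- split(intervals, intervals$contig)
  lookup <- function(contig, pos) {
    tab <- iv_index[[contig]]
    if (is.null(tab)) return(NA_integer_)
    i <- findInterval(pos, tab$start)
    if (i == 0L || pos >= tab$end[i]) return(NA_integer_)
    tab$interval_id[i]
  }
  mate_of <- function(contig, blocks) {
    ivs <- integer(0)
    for (r in seq_len(nrow(blocks))) {
      a <- lookup(contig, blocks[r, 1L])
      b <- lookup(contig, blocks[r, 2L] - 1L)
      if (is.na(a) || is.na(b)) return(NULL)
      ivs <- c(ivs, seq(a, b))
    }
    list(ivs = unique(ivs), juncs = blocks_to_introns(blocks))
  }

  acc <- new.env(parent = emptyenv())
  n_ignored <- 0L
  add <- function(key, contig, strand, mates, pair_iv) {
    cur <- acc[[key]]
    if (is.null(cur)) {
      acc[[key]] <- list(contig = contig, strand = strand, mates = mates,
                         pair_iv = pair_iv, multiplicity = 1L)
    } else {
      cur$multiplicity <- cur$multiplicity + 1L
      acc[[key]] <- cur
    }
  }

  for (i in seq_len(nrow(singles))) {
    m <- mate_of(singles$contig[i], singles$blocks[[i]])
    if (is.null(m)) { n_ignored <- n_ignored + 1L; next }
    key <- paste(singles$contig[i], paste(m$ivs, collapse = ","),
                 chain_key(m$juncs), sep = ";")
    add(key, singles$contig[i], singles$strand[i], list(m), NULL)
  }
  for (i in seq_len(nrow(pairs))) {
    ml <- mate_of(pairs$contig[i], pairs$left_blocks[[i]])
    mr <- mate_of(pairs$contig[i], pairs$right_blocks[[i]])
    if (is.null(ml) || is.null(mr)) { n_ignored <- n_ignored + 1L; next }
    pair_iv <- c(lookup(pairs$contig[i], pairs$left_start[i]),
                 lookup(pairs$contig[i], pairs$right_end[i] - 1L))
    key <- paste(pairs$contig[i],
                 paste(ml$ivs, collapse = ","), chain_key(ml$juncs),
                 paste(mr$ivs, collapse = ","), chain_key(mr$juncs),
                 paste(pair_iv, collapse = "-"), sep = ";")
    add(key, pairs$contig[i], pairs$strand[i], list(ml, mr), pair_iv)
  }

  keys <- sort(ls(acc))
  out <- purrr::map(keys, function(k) {
    x <- acc[[k]]
    tibble::tibble(contig = x$contig, strand = x$strand,
                   mates = list(x$mates), pair_iv = list(x$pair_iv),
                   multiplicity = x$multiplicity)
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0L) {
    out <- tibble::tibble(contig = character(), strand = character(),
                          mates = list(), pair_iv = list(),
                          multiplicity = integer())
  }
  out <- dplyr::mutate(out, constraint_id = dplyr::row_number(),
                       .before = 1L)
  class(out) <- c("constraint_set", class(out))
  attr(out, "n_ignored") <- n_ignored
  out
}

# chain of global interval ids for one transcript (exon matrix + contig)
iv_chain_of <- function(exm, contig, intervals) {
  tab <- intervals[intervals$contig == contig, ]
  out <- integer(0)
  for (r in seq_len(nrow(exm))) {
    i <- findInterval(exm[r, 1L], tab$start)
    j <- findInterval(exm[r, 2L] - 1L, tab$start)
    if (i == 0L || j == 0L) next
    out <- c(out, tab$interval_id[i:j])
  }
  out
}

#' Does a transcript satisfy a constraint?
#'
#' True when the transcript contains every interval of the constraint, each
#' mate's intervals appear as a consecutive run of the transcript's interval
#' chain with the transcript's introns inside that run equal to the mate's
#' junction chain (no extra intron interleaved), and, for pair constraints
#' with fragment statistics available, the achievable fragment length
#' between the pair's start and end intervals along the transcript
#' intersects the admissible window `f_l - 2 f_sigma .. f_l + 2 f_sigma`.
#'
#' @param transcript One row of a candidate-transcript tibble (from
#'   [enumerate_maximal_paths()]).
#' @param constraint One row of a `constraint_set`.
#' @param intervals Global interval tibble.
#' @param stats Optional `fragment_stats`; `NULL` skips the pair window.
#' @return Logical.
#' @export
satisfies_constraint <- function(transcript, constraint, intervals,
                                 stats = NULL) {
  if (transcript$contig != constraint$contig) return(FALSE)
  if (!strand_compatible(transcript$strand, constraint$strand)) {
    return(FALSE)
  }
  chain <- iv_chain_of(transcript$exons[[1L]], transcript$contig, intervals)
  satisfies_chain(chain, constraint, intervals, stats)
}

# core check against a precomputed interval chain (used by the bulk builder)
satisfies_chain <- function(chain, constraint, intervals, stats) {
  for (mate in constraint$mates[[1L]]) {
    idx <- match(mate$ivs, chain)
    if (anyNA(idx)) return(FALSE)
    lo <- min(idx); hi <- max(idx)
    if (hi - lo + 1L != length(mate$ivs)) return(FALSE)
    run <- chain[lo:hi]
    if (!identical(sort(run), sort(mate$ivs))) return(FALSE)
    # introns inside the run: gaps between genomically non-adjacent
    # consecutive chain intervals must match the mate's junctions
    if (length(run) > 1L) {
      s <- intervals$start[run]
      e <- intervals$end[run]
      gaps <- which(e[-length(run)] != s[-1L])
      tj <- cbind(e[gaps], s[gaps + 1L])
      if (!identical(chain_key(tj), chain_key(mate$juncs))) return(FALSE)
    } else if (nrow(mate$juncs) > 0L) {
      return(FALSE)
    }
  }
  pv <- constraint$pair_iv[[1L]]
  if (!is.null(pv) && !is.null(stats)) {
    rng <- chain_fragment_range(chain, pv[1L], pv[2L], intervals)
    if (is.null(rng)) return(FALSE)
    win <- frag_window(stats)
    if (rng[1] > win[2] || rng[2] < win[1]) return(FALSE)
  }
  TRUE
}

# min/max distance from a point in interval i to a point in interval j
# along a fixed transcript interval chain
chain_fragment_range <- function(chain, i, j, intervals) {
  pi <- match(i, chain); pj <- match(j, chain)
  if (is.na(pi) || is.na(pj) || pj < pi) return(NULL)
  len <- intervals$len[chain]
  if (pi == pj) return(c(1, len[pi]))
  mid <- if (pj - pi > 1L) sum(len[(pi + 1L):(pj - 1L)]) else 0
  c(mid + 2, len[pi] + mid + len[pj])
}

#' Build the constraint-transcript satisfaction graph
#'
#' Computes the bipartite relation between constraints and candidate
#' transcripts (an edge where the transcript satisfies the constraint).
#'
#' @param transcripts Candidate transcript tibble.
#' @param constraints A `constraint_set`.
#' @param intervals Global interval tibble.
#' @param stats Optional `fragment_stats`.
#' @return A list of class `constraint_graph`: `constraints`, `transcripts`,
#'   `edges` (tibble `constraint_id`, `transcript_id`).
#' @export
build_constraint_graph <- function(transcripts, constraints, intervals,
                                   stats = NULL) {
  chains <- purrr::map2(transcripts$exons, transcripts$contig,
                        ~ iv_chain_of(.x, .y, intervals))
  edges <- list()
  for (ci in seq_len(nrow(constraints))) {
    con <- constraints[ci, ]
    # only transcripts containing the constraint's first interval can match
    for (ti in seq_len(nrow(transcripts))) {
      if (transcripts$contig[ti] != con$contig) next
      if (!strand_compatible(transcripts$strand[ti], con$strand)) next
      if (satisfies_chain(chains[[ti]], con, intervals, stats)) {
        edges[[length(edges) + 1L]] <-
          c(con$constraint_id, transcripts$transcript_id[ti])
      }
    }
  }
  edges <- if (length(edges)) {
    m <- do.call(rbind, edges)
    tibble::tibble(constraint_id = m[, 1L], transcript_id = m[, 2L])
  } else {
    tibble::tibble(constraint_id = integer(), transcript_id = integer())
  }
  structure(list(constraints = constraints, transcripts = transcripts,
                 edges = edges),
            class = "constraint_graph")
}

#' Remove constraints satisfied by no transcript
#'
#' Constraints with no satisfying transcript are likely read or alignment
#' artifacts and are dropped before selection.
#'
#' @param graph A `constraint_graph`.
#' @return The pruned graph, with attribute `n_removed`.
#' @export
prune_unsatisfiable <- function(graph) {
  ok <- graph$constraints$constraint_id %in% graph$edges$constraint_id
  out <- graph
  out$constraints <- graph$constraints[ok, ]
  attr(out, "n_removed") <- sum(!ok)
  out
}

#' Select transcripts by greedy set cover
#'
#' Repeatedly adds the transcript satisfying the largest number of not yet
#' covered constraints until all are covered (the classical ln-factor greedy
#' approximation). Ties are broken by smaller weight, then more introns,
#' then smaller transcript id.
#'
#' @param graph A pruned `constraint_graph`.
#' @return Integer vector of selected `transcript_id`s, in selection order.
#' @export
greedy_set_cover <- function(graph) {
  w <- rep(1, nrow(graph$transcripts))
  names(w) <- graph$transcripts$transcript_id
  weighted_greedy_set_cover(graph, w)
}

#' Select transcripts by weighted greedy set cover
#'
#' Like [greedy_set_cover()] but each step adds the transcript minimising
#' weight divided by the number of newly covered constraints
#' (cost-effectiveness rule). With all weights equal this reduces exactly to
#' the unweighted greedy, including tie-breaking.
#'
#' @param graph A pruned `constraint_graph`.
#' @param weights Named numeric vector (names = transcript ids) of positive
#'   weights, e.g. from [transcript_weights()].
#' @return Integer vector of selected `transcript_id`s, in selection order.
#' @export
weighted_greedy_set_cover <- function(graph, weights) {
  cons <- graph$constraints$constraint_id
  edges <- graph$edges
  tids <- graph$transcripts$transcript_id
  n_intr <- purrr::map_int(graph$transcripts$introns, nrow)
  names(n_intr) <- tids
  cover <- split(edges$constraint_id, edges$transcript_id)
  uncovered <- cons
  selected <- integer(0)
  while (length(uncovered) > 0L) {
    best <- NULL
    for (t in names(cover)) {
      new <- sum(cover[[t]] %in% uncovered)
      if (new == 0L) next
      wt <- unname(weights[[t]])
      ratio <- wt / new
      cand <- list(t = as.integer(t), ratio = ratio, w = wt,
                   ni = n_intr[[t]])
      if (is.null(best) ||
          ratio < best$ratio - 1e-12 ||
          (abs(ratio - best$ratio) <= 1e-12 &&
             (cand$w < best$w - 1e-12 ||
                (abs(cand$w - best$w) <= 1e-12 &&
                   (cand$ni > best$ni ||
                      (cand$ni == best$ni && cand$t < best$t)))))) {
        best <- cand
      }
    }
    if (is.null(best)) break  # cannot happen on a pruned graph
    selected <- c(selected, best$t)
    uncovered <- setdiff(uncovered, cover[[as.character(best$t)]])
  }
  selected
}

#' Collect consecutive intron pairs from an annotation
#'
#' For every annotated transcript with at least two introns, each adjacent
#' intron pair is added to the evidence set used to down-weight novel
#' intron-pair combinations in the weighted selection mode.
#'
#' @param annotation Path to a GTF file with exon features carrying
#'   `transcript_id` attributes, or a transcript tibble from
#'   [read_gtf_transcripts()].
#' @return A character set of intron-pair keys.
#' @export
load_evidence_intron_pairs <- function(annotation) {
  tx <- if (is.character(annotation)) read_gtf_transcripts(annotation)
        else annotation
  keys <- character(0)
  for (i in seq_len(nrow(tx))) {
    m <- tx$introns[[i]]
    if (is.null(m) || nrow(m) < 2L) next
    keys <- c(keys, intron_pair_keys(m, tx$contig[i], tx$strand[i]))
  }
  unique(keys)
}

intron_pair_keys <- function(m, contig, strand) {
  k <- nrow(m)
  if (k < 2L) return(character(0))
  paste0(contig, ":", strand, ":",
         m[-k, 1L], "-", m[-k, 2L], "|", m[-1L, 1L], "-", m[-1L, 2L])
}

#' Annotation-based transcript weights
#'
#' A transcript's weight is `1 + lambda * (1 - q)` where `q` is the fraction
#' of its consecutive intron pairs found in the evidence set. Transcripts
#' with fewer than two introns have no intron pairs; the measure is
#' undefined for them and they receive weight 1.
#'
#' @param transcripts Candidate transcript tibble.
#' @param evidence Character set from [load_evidence_intron_pairs()].
#' @param lambda Penalty scale (> 0); weights lie in `[1, 1 + lambda]`.
#' @return The transcript tibble with `evidence_fraction` and `weight`
#'   columns added.
#' @export
transcript_weights <- function(transcripts, evidence, lambda = 1) {
  stopifnot(lambda > 0)
  ef <- purrr::pmap_dbl(
    list(transcripts$introns, transcripts$contig, transcripts$strand),
    function(m, contig, strand) {
      keys <- intron_pair_keys(m, contig, strand)
      if (length(keys) == 0L) return(1)
      mean(keys %in% evidence)
    })
  dplyr::mutate(transcripts, evidence_fraction = ef,
                weight = 1 + lambda * (1 - ef))
}
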
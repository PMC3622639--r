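#' Partition a region into intervals at splice-site boundaries
#'
#' `k` boundaries strictly inside the region produce `k + 1` intervals that
#' tile it exactly. Each interval carries its length and mean read coverage
#' (aligned bases of read blocks overlapping the interval, divided by the
#' interval length).
#'
#' @param region One-row region tibble from [detect_regions()].
#' @param boundaries Sorted positions strictly inside the region (use
#'   `extract_splice_sites()$pos`).
#' @param reads Reads tibble (or `alignment_set`) supplying coverage.
#' @return A tibble with columns `iv` (1-based local index), `start`, `end`,
#'   `len`, `cbar`.
#' @export
partition_intervals <- function(region, boundaries, reads) {
  if (inherits(reads, "alignment_set")) reads <- reads$reads
  bnd <- sort(unique(as.integer(boundaries)))
  stopifnot(all(bnd > region$start), all(bnd < region$end))
  edges <- c(region$start, bnd, region$end)
  k <- length(edges) - 1L
  iv <- tibble::tibble(iv = seq_len(k),
                       start = edges[-length(edges)],
                       end = edges[-1L])
  iv$len <- iv$end - iv$start

  blks <- do.call(rbind, reads$blocks[reads$contig == region$contig])
  if (is.null(blks) || nrow(blks) == 0L) {
    iv$cbar <- 0
    return(iv)
  }
  ir <- IRanges::IRanges(start = blks[, 1L] + 1L, end = blks[, 2L])
  cov <- IRanges::coverage(ir)
  covlen <- length(cov)
  iv$cbar <- purrr::map2_dbl(iv$start, iv$end, function(s, e) {
    s1 <- s + 1L
    e1 <- min(e, covlen)
    if (s1 > e1) return(0)
    v <- IRanges::Views(cov, start = s1, end = e1)
    IRanges::viewSums(v) / (e - s)
  })
  iv
}

#' Enumerate candidate exons for a region
#'
#' Candidate exon left boundaries are the region start and every acceptor
#' boundary; right boundaries are every donor boundary and the region end.
#' One candidate is produced for every left/right pair with `left < right`.
#'
#' @param region One-row region tibble.
#' @param intervals Interval tibble from [partition_intervals()].
#' @param sites Splice-site tibble from [extract_splice_sites()] (already
#'   filtered to the strand being processed).
#' @return A tibble of candidates: `cand`, `start`, `end`, `first_iv`,
#'   `last_iv`, `left_kind`, `right_kind`.
#' @export
enumerate_candidate_exons <- function(region, intervals, sites) {
  lefts <- tibble::tibble(
    pos = c(region$start, sites$pos[sites$kind == "acceptor"]),
    kind = c("region_edge",
             rep("acceptor", sum(sites$kind == "acceptor"))))
  rights <- tibble::tibble(
    pos = c(sites$pos[sites$kind == "donor"], region$end),
    kind = c(rep("donor", sum(sites$kind == "donor")), "region_edge"))
  lefts <- dplyr::distinct(lefts)
  rights <- dplyr::distinct(rights)
  grid <- tidyr::expand_grid(l = seq_len(nrow(lefts)),
                             r = seq_len(nrow(rights)))
  grid <- grid[lefts$pos[grid$l] < rights$pos[grid$r], ]
  out <- tibble::tibble(
    start = lefts$pos[grid$l],
    end = rights$pos[grid$r],
    left_kind = lefts$kind[grid$l],
    right_kind = rights$kind[grid$r])
  out <- dplyr::arrange(out, .data$start, .data$end)
  out$cand <- seq_len(nrow(out))
  out$first_iv <- findInterval(out$start, intervals$start)
  out$last_iv <- findInterval(out$end - 1L, intervals$start)
  dplyr::select(out, "cand", "start", "end", "first_iv", "last_iv",
                "left_kind", "right_kind")
}

# ---- read / pair patterns used by the feasibility conditions -------------

# Deduplicated in-region read patterns. Each pattern records the read blocks
# falling inside the region, the junctions between them, and whether the read
# enters/leaves the region through a junction (boundary then must be an exact
# exon boundary).
compile_read_patterns <- function(region, reads, strand = NULL) {
  r <- reads[reads$contig == region$contig, ]
  if (!is.null(strand) && !(strand %in% c(".", "*"))) {
    r <- r[r$strand %in% c(strand, "*"), ]
  }
  pats <- list()
  for (i in seq_len(nrow(r))) {
    b <- r$blocks[[i]]
    inside <- which(b[, 1L] >= region$start & b[, 2L] <= region$end)
    if (length(inside) == 0L) next
    # blocks are sorted; the in-region ones form a consecutive run
    bb <- b[inside, , drop = FALSE]
    juncs <- blocks_to_introns(bb)
    left_entry <- inside[1L] > 1L
    right_exit <- inside[length(inside)] < nrow(b)
    key <- paste(chain_key(bb), chain_key(juncs), left_entry, right_exit,
                 sep = ";")
    if (is.null(pats[[key]])) {
      pats[[key]] <- list(blocks = bb, juncs = juncs,
                          left_entry = left_entry, right_exit = right_exit)
    }
  }
  unname(pats)
}

# For one pattern, the list of candidate-id sets of which the combination
# must contain at least one each (condition 2). Returns NULL if the pattern
# can never be satisfied by any combination of the given candidates.
pattern_required_sets <- function(pat, cands) {
  b <- pat$blocks
  k <- nrow(b)
  sets <- list()
  if (k == 1L) {
    ok <- cands$start <= b[1L, 1L] & cands$end >= b[1L, 2L]
    if (pat$left_entry) ok <- ok & cands$start == b[1L, 1L]
    if (pat$right_exit) ok <- ok & cands$end == b[1L, 2L]
    sets[[1L]] <- cands$cand[ok]
  } else {
    j <- pat$juncs
    first_ok <- cands$end == j[1L, 1L] & cands$start <= b[1L, 1L]
    if (pat$left_entry) first_ok <- first_ok & cands$start == b[1L, 1L]
    sets[[1L]] <- cands$cand[first_ok]
    if (k > 2L) {
      for (m in 2:(k - 1L)) {
        mid_ok <- cands$start == j[m - 1L, 2L] & cands$end == j[m, 1L]
        sets[[m]] <- cands$cand[mid_ok]
      }
    }
    last_ok <- cands$start == j[k - 1L, 2L] & cands$end >= b[k, 2L]
    if (pat$right_exit) last_ok <- last_ok & cands$end == b[k, 2L]
    sets[[k]] <- cands$cand[last_ok]
  }
  if (any(lengths(sets) == 0L)) return(NULL)
  sets
}

# pairs with both mates inside the region, summarised two ways:
#  - classes: (interval of left-read start, interval of right-read end)
#    with multiplicities, for the fragment-length penalty
#  - mates: deduplicated (left mate, right mate) block/junction patterns
#    for condition 3 (the two mates must have compatible alignments)
compile_pair_info <- function(region, intervals, pairs, strand = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(list(classes = tibble::tibble(iv_i = integer(), iv_j = integer(),
                                         n = integer()),
                mates = list(), n_total = 0L))
  }
  p <- pairs[pairs$contig == region$contig &
               pairs$left_start >= region$start &
               pairs$right_end <= region$end, ]
  if (!is.null(strand) && !(strand %in% c(".", "*"))) {
    p <- p[p$strand %in% c(strand, "*"), ]
  }
  if (nrow(p) == 0L) {
    return(list(classes = tibble::tibble(iv_i = integer(), iv_j = integer(),
                                         n = integer()),
                mates = list(), n_total = 0L))
  }
  iv_of <- function(pos) findInterval(pos, intervals$start)
  p$iv_i <- iv_of(p$left_start)
  p$iv_j <- iv_of(p$right_end - 1L)
  classes <- p |>
    dplyr::count(.data$iv_i, .data$iv_j, name = "n")
  mates <- list()
  for (i in seq_len(nrow(p))) {
    lb <- p$left_blocks[[i]]; rb <- p$right_blocks[[i]]
    key <- paste(chain_key(lb), chain_key(rb), sep = ";")
    if (is.null(mates[[key]])) {
      mates[[key]] <- list(
        left = list(blocks = lb, juncs = blocks_to_introns(lb),
                    left_entry = FALSE, right_exit = FALSE),
        right = list(blocks = rb, juncs = blocks_to_introns(rb),
                     left_entry = FALSE, right_exit = FALSE))
    }
  }
  list(classes = classes, mates = unname(mates), n_total = nrow(p))
}

# condition 3 exon sets for one mate pair: the candidates able to terminate
# the left mate's exon chain, and those able to start the right mate's
pair_join_sets <- function(mate_pair, cands) {
  ls <- pattern_required_sets(mate_pair$left, cands)
  rs <- pattern_required_sets(mate_pair$right, cands)
  if (is.null(ls) || is.null(rs)) return(NULL)
  list(from = ls[[length(ls)]], to = rs[[1L]])
}

# candidate-to-candidate intron links: a supported junction whose donor is
# the left exon's end and whose acceptor is the right exon's start
candidate_links <- function(cands, junctions, contig, strand = NULL) {
  n <- nrow(cands)
  links <- matrix(FALSE, n, n)
  j <- junctions[junctions$contig == contig, ]
  if (!is.null(strand) && !(strand %in% c(".", "*"))) {
    j <- j[strand_compatible(j$strand, strand), ]
  }
  for (r in seq_len(nrow(j))) {
    from <- which(cands$end == j$donor[r])
    to <- which(cands$start == j$acceptor[r])
    if (length(from) && length(to)) links[from, to] <- TRUE
  }
  links
}

# can any exon in `from` reach any exon in `to` along links, within members?
links_reachable <- function(from, to, members, links) {
  from <- intersect(from, members)
  to <- intersect(to, members)
  if (length(from) == 0L || length(to) == 0L) return(FALSE)
  if (length(intersect(from, to))) return(TRUE)
  seen <- from
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(members[colSums(links[frontier, members,
                                         drop = FALSE]) > 0L], seen)
    if (any(nxt %in% to)) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Check the feasibility conditions for a combination of candidate exons
#'
#' A combination is feasible when (1) every splice-site boundary of the
#' region is an endpoint of at least one member exon, (2) every read is
#' compatible with the members (unspliced reads lie inside a member exon;
#' spliced reads map onto a chain of members whose boundaries match the
#' read's junctions), and (3) the two mates of each pair have compatible
#' alignments: some member exon able to terminate the left mate's exon
#' chain equals, or reaches through junction-linked non-overlapping member
#' exons, a member exon able to start the right mate's chain.
#'
#' @param combo Integer vector of candidate ids (rows of `cands`) in the
#'   combination.
#' @param cands Candidate tibble from [enumerate_candidate_exons()].
#' @param region,intervals Region and its intervals.
#' @param reads,pairs,junctions Tables from [read_alignments()].
#' @param strand Strand being processed (`"+"`, `"-"` or `"."`).
#' @return `TRUE`, or `FALSE` with a `reason` attribute
#'   (`"uncovered_splice_site"`, `"incompatible_read"`,
#'   `"incompatible_pair"`).
#' @export
is_feasible_combination <- function(combo, cands, region, intervals, reads,
                                    pairs = NULL, junctions = NULL,
                                    strand = ".") {
  sites <- infer_sites_from_cands(cands, region)
  for (s in seq_len(nrow(sites))) {
    touch <- if (sites$kind[s] == "donor") {
      cands$cand[cands$end == sites$pos[s]]
    } else {
      cands$cand[cands$start == sites$pos[s]]
    }
    if (!any(touch %in% combo)) {
      return(structure(FALSE, reason = "uncovered_splice_site"))
    }
  }
  if (inherits(reads, "alignment_set")) {
    if (is.null(pairs)) pairs <- reads$pairs
    if (is.null(junctions)) junctions <- reads$junctions
    reads <- reads$reads
  }
  pats <- compile_read_patterns(region, reads, strand)
  for (pat in pats) {
    sets <- pattern_required_sets(pat, cands)
    if (is.null(sets) || !all(purrr::map_lgl(sets, ~ any(.x %in% combo)))) {
      return(structure(FALSE, reason = "incompatible_read"))
    }
  }
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    info <- compile_pair_info(region, intervals, pairs, strand)
    links <- candidate_links(cands, junctions %||%
                               tibble::tibble(contig = character(),
                                              donor = integer(),
                                              acceptor = integer(),
                                              strand = character()),
                             region$contig, strand)
    for (mp in info$mates) {
      js <- pair_join_sets(mp, cands)
      if (is.null(js) || !links_reachable(js$from, js$to, combo, links)) {
        return(structure(FALSE, reason = "incompatible_pair"))
      }
    }
  }
  TRUE
}

# recover the labeled splice sites implied by a candidate table (every
# candidate boundary that is not a region edge is a splice site)
infer_sites_from_cands <- function(cands, region) {
  dplyr::bind_rows(
    tibble::tibble(pos = unique(cands$end[cands$right_kind == "donor"]),
                   kind = "donor"),
    tibble::tibble(pos = unique(cands$start[cands$left_kind == "acceptor"]),
                   kind = "acceptor"))
}

# ---- the linear program ---------------------------------------------------

#' Solve the subexon-coverage linear program for one exon combination
#'
#' One decision variable `c[i, j]` per subexon (exon `i` restricted to
#' interval `j`), one slack per additivity constraint (per interval) and one
#' per continuity constraint (per adjacent interval pair within an exon).
#' Additivity requires the subexon coverages in an interval to sum to the
#' observed interval coverage up to slack; continuity requires adjacent
#' subexons of one exon to have similar coverage; conservation fixes the
#' total coverage mass exactly; every subexon coverage must be at least
#' `lower_bound`. The objective minimises the total slack.
#'
#' If the system is infeasible with the default `lower_bound = 1` (possible
#' at low coverage, where conservation and the lower bound conflict), it is
#' retried once with `lower_bound = 0`.
#'
#' @param exons Tibble of member exons (rows of the candidate table).
#' @param intervals Interval tibble with `len` and `cbar`.
#' @param lower_bound Minimum subexon coverage.
#' @return A list: `status` (`"optimal"` or `"infeasible"`), `objective`,
#'   `c` (tibble `exon`, `iv`, `coverage`), `eps` (all slack values),
#'   `lower_bound_used`.
#' @export
solve_coverage_lp <- function(exons, intervals, lower_bound = 1) {
  cells <- dplyr::bind_rows(purrr::map(seq_len(nrow(exons)), function(i) {
    tibble::tibble(exon = i,
                   iv = seq(exons$first_iv[i], exons$last_iv[i]))
  }))
  ncell <- nrow(cells)
  k <- nrow(intervals)
  cont <- cells |>
    dplyr::group_by(.data$exon) |>
    dplyr::filter(dplyr::n() > 1L) |>
    dplyr::mutate(nxt = dplyr::lead(.data$iv)) |>
    dplyr::filter(!is.na(.data$nxt)) |>
    dplyr::ungroup()
  ncont <- nrow(cont)
  nv <- ncell + k + ncont
  obj <- c(rep(0, ncell), rep(1, k + ncont))

  cell_idx <- function(e, j) which(cells$exon == e & cells$iv == j)
  # additivity rows
  A_add <- matrix(0, k, nv)
  for (j in seq_len(k)) {
    in_iv <- which(cells$iv == j)
    A_add[j, in_iv] <- 1
    A_add[j, ncell + j] <- -1
  }
  b_add <- intervals$cbar
  # continuity rows (|c_a - c_b| <= eps)
  A_c1 <- A_c2 <- matrix(0, ncont, nv)
  for (r in seq_len(ncont)) {
    a <- cell_idx(cont$exon[r], cont$iv[r])
    b <- cell_idx(cont$exon[r], cont$nxt[r])
    s <- ncell + k + r
    A_c1[r, c(a, b, s)] <- c(1, -1, -1)
    A_c2[r, c(a, b, s)] <- c(-1, 1, -1)
  }
  # conservation
  A_eq <- matrix(0, 1, nv)
  A_eq[1, seq_len(ncell)] <- intervals$len[cells$iv]
  b_eq <- sum(intervals$cbar * intervals$len)

  solve_at <- function(lb) {
    A1 <- rbind(A_add, A_c1, A_c2)        # <=
    b1 <- c(b_add, rep(0, 2 * ncont))
    A2 <- matrix(0, k, nv)                # sum c + eps >= cbar

    for (j in seq_len(k)) {
      A2[j, which(cells$iv == j)] <- 1
      A2[j, ncell + j] <- 1
    }
    b2 <- b_add
    if (lb > 0) {
      Alb <- matrix(0, ncell, nv)
      Alb[cbind(seq_len(ncell), seq_len(ncell))] <- 1
      A2 <- rbind(A2, Alb)
      b2 <- c(b2, rep(lb, ncell))
    }
    res <- tryCatch(
      boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                    A3 = A_eq, b3 = b_eq, maxi = FALSE,
                    n.iter = 50 * (nv + 2)),
      error = function(e) NULL)
    if (is.null(res) || res$solved != 1L) return(NULL)
    res
  }

  lb_used <- lower_bound
  res <- solve_at(lower_bound)
  if (is.null(res) && lower_bound > 0) {
    lb_used <- 0
    res <- solve_at(0)
  }
  if (is.null(res)) {
    return(list(status = "infeasible", objective = Inf, c = NULL,
                eps = NULL, lower_bound_used = lb_used))
  }
  soln <- as.numeric(res$soln)
  cells$coverage <- soln[seq_len(ncell)]
  list(status = "optimal",
       objective = as.numeric(res$value),
       c = cells,
       eps = soln[ncell + seq_len(k + ncont)],
       lower_bound_used = lb_used)
}

# ---- paired-end feasibility penalty --------------------------------------

#' Fragment-length feasibility penalty for an exon combination
#'
#' For each pair class (left-read start interval `i`, right-read end
#' interval `j`), computes the minimal and maximal fragment length achievable
#' along chains of junction-linked member exons. If the achievable range
#' misses the admissible window `f_l - 2 f_sigma .. f_l + 2 f_sigma`
#' entirely, the class contributes its fraction of pairs `n[i,j] / N` to the
#' penalty.
#'
#' @param exons Member exon tibble (with `first_iv`, `last_iv`, `start`,
#'   `end`).
#' @param classes Pair-class tibble (`iv_i`, `iv_j`, `n`).
#' @param n_total Total number of pairs in the region.
#' @param stats `fragment_stats` for the library.
#' @param intervals Interval tibble.
#' @param links Logical adjacency matrix over `exons` rows (junction links).
#' @return Penalty in `[0, 1]`; 0 when `classes` is empty or `stats` is
#'   `NULL` (single-end mode).
#' @export
pair_feasibility_penalty <- function(exons, classes, n_total, stats,
                                     intervals, links) {
  if (is.null(stats) || nrow(classes) == 0L || n_total == 0L) return(0)
  win <- frag_window(stats)
  pen <- 0
  for (r in seq_len(nrow(classes))) {
    i <- classes$iv_i[r]; j <- classes$iv_j[r]
    rng <- achievable_fragment_range(exons, i, j, intervals, links)
    feasible <- !is.null(rng) && rng[1] <= win[2] && rng[2] >= win[1]
    if (!feasible) pen <- pen + classes$n[r] / n_total
  }
  pen
}

# min/max fragment length from a point in interval i to a point in interval
# j over all chains of linked member exons; NULL if no chain exists
achievable_fragment_range <- function(exons, i, j, intervals, links) {
  holds_i <- which(exons$first_iv <= i & exons$last_iv >= i)
  holds_j <- which(exons$first_iv <= j & exons$last_iv >= j)
  if (length(holds_i) == 0L || length(holds_j) == 0L) return(NULL)
  iv_i <- intervals[i, ]; iv_j <- intervals[j, ]
  best <- NULL
  note <- function(lo, hi) {
    lo <- max(lo, 1)
    if (is.null(best)) best <<- c(lo, hi)
    else best <<- c(min(best[1], lo), max(best[2], hi))
  }
  # same-exon case
  for (e in intersect(holds_i, holds_j)) {
    note(iv_j$start - iv_i$end + 2, iv_j$end - iv_i$start)
  }
  # chains E1 -> ... -> Ek (DFS over links; graphs here are tiny)
  recurse <- function(path, mid) {
    last <- path[length(path)]
    nxt <- which(links[last, ])
    for (e in nxt) {
      if (e %in% path) next
      if (e %in% holds_j) {
        e1 <- exons[path[1L], ]; ek <- exons[e, ]
        note((e1$end - iv_i$end + 1) + mid + (iv_j$start + 1 - ek$start),
             (e1$end - iv_i$start) + mid + (iv_j$end - ek$start))
      }
      recurse(c(path, e), mid + (exons$end[e] - exons$start[e]))
    }
  }
  for (e0 in holds_i) recurse(e0, 0)
  # correct mid for terminal exon double-count: handled by construction --
  # mid passed to note() excludes E1 and Ek because it accumulates only
  # exons strictly between them (Ek's length is added after the call).
  best
}

# ---- combination enumeration and selection -------------------------------

#' Choose the best-scoring exon combination for a region
#'
#' Enumerates feasible combinations of candidate exons (all subsets while
#' the candidate count is within `cap_candidates`; above the cap the
#' candidate list is first restricted to read-evidenced exons plus minimal
#' completions), scores each as the LP objective plus, for paired data, the
#' fragment-length penalty, and returns the minimal-score combination.
#' Ties are broken by fewest exons, then lexicographically on exon
#' boundaries. If no combination is feasible the whole region is emitted as
#' a single exon with a warning.
#'
#' @param region,intervals,sites Region, its intervals and splice sites.
#' @param reads,pairs,junctions Tables from [read_alignments()].
#' @param stats Optional `fragment_stats`; `NULL` disables the pair penalty.
#' @param config List of tuning knobs: `lp_lower_bound` (default 1),
#'   `cap_candidates` (16), `cap_sites` (12).
#' @return A list with `exons` (chosen exon tibble with `strand`), `score`,
#'   `n_combinations` examined, and `fallback` flag.
#' @export
select_exon_set <- function(region, intervals, sites, reads, pairs = NULL,
                            junctions = NULL, stats = NULL,
                            config = list()) {
  if (inherits(reads, "alignment_set")) {
    if (is.null(pairs)) pairs <- reads$pairs
    if (is.null(junctions)) junctions <- reads$junctions
    reads <- reads$reads
  }
  cfg <- utils::modifyList(list(lp_lower_bound = 1, cap_candidates = 16L,
                                cap_sites = 12L), config)
  strands <- unique(sites$strand[sites$strand != "*"])
  if (length(strands) == 0L) strands <- "."
  chosen <- list()
  total_score <- 0
  ncomb <- 0L
  fallback <- FALSE
  for (s in strands) {
    sites_s <- sites[strand_compatible(sites$strand, s), ]
    res <- select_exon_set_strand(region, intervals, sites_s, reads, pairs,
                                  junctions, stats, cfg, s)
    if (res$fallback) fallback <- TRUE
    total_score <- total_score + res$score
    ncomb <- ncomb + res$n_combinations
    chosen[[s]] <- dplyr::mutate(res$exons, strand = s)
  }
  exons <- dplyr::bind_rows(chosen) |>
    dplyr::arrange(.data$start, .data$end) |>
    dplyr::mutate(region_id = region$region_id, contig = region$contig)
  list(exons = exons, score = total_score, n_combinations = ncomb,
       fallback = fallback)
}

select_exon_set_strand <- function(region, intervals, sites, reads, pairs,
                                   junctions, stats, cfg, strand) {
  cands <- enumerate_candidate_exons(region, intervals, sites)
  whole <- tibble::tibble(cand = 1L, start = region$start, end = region$end,
                          first_iv = 1L, last_iv = nrow(intervals),
                          left_kind = "region_edge",
                          right_kind = "region_edge")
  if (nrow(sites) == 0L || nrow(cands) == 0L) {
    lp <- solve_coverage_lp(whole, intervals, cfg$lp_lower_bound)
    return(list(exons = whole, score = lp$objective, n_combinations = 1L,
                fallback = FALSE))
  }
  pats <- compile_read_patterns(region, reads, strand)
  if (nrow(cands) > cfg$cap_candidates ||
      nrow(sites) > cfg$cap_sites) {
    cands <- restrict_candidates(cands, pats, sites, region, cfg)
  }
  n <- nrow(cands)
  cands$cand <- seq_len(n)

  # bitmask machinery (n <= 16 by the cap, restriction may still exceed it
  # in pathological regions -- then fall back to the whole-region exon)
  if (n > 24L) {
    warning("region ", region$region_id, ": ", n,
            " candidate exons after restriction; emitting whole region")
    lp <- solve_coverage_lp(whole, intervals, cfg$lp_lower_bound)
    return(list(exons = whole, score = lp$objective, n_combinations = 0L,
                fallback = TRUE))
  }
  bits <- as.integer(2^(seq_len(n) - 1L))
  mask_of <- function(idx) as.integer(sum(bits[idx]))
  site_masks <- purrr::map_int(seq_len(nrow(sites)), function(s) {
    touch <- if (sites$kind[s] == "donor") which(cands$end == sites$pos[s])
             else which(cands$start == sites$pos[s])
    mask_of(touch)
  })
  req_masks <- list()
  unsat_pattern <- FALSE
  for (pat in pats) {
    sets <- pattern_required_sets(pat, cands)
    if (is.null(sets)) { unsat_pattern <- TRUE; break }
    req_masks <- c(req_masks, purrr::map(sets, mask_of))
  }
  req_masks <- unique(req_masks)
  info <- compile_pair_info(region, intervals, pairs %||%
                              tibble::tibble(contig = character()), strand)
  links <- candidate_links(cands, junctions %||%
                             tibble::tibble(contig = character(),
                                            donor = integer(),
                                            acceptor = integer(),
                                            strand = character()),
                           region$contig, strand)
  inner_sets <- purrr::map(info$mates, pair_join_sets, cands = cands)
  if (length(inner_sets) &&
      any(purrr::map_lgl(inner_sets, is.null))) {
    unsat_pattern <- TRUE
  }
  inner_sets <- unique(inner_sets)

  req_masks <- as.integer(unlist(req_masks))
  best <- NULL
  ncomb <- 0L
  if (!unsat_pattern) {
    for (mask in seq_len(2L^n - 1L)) {
      if (any(bitwAnd(mask, site_masks) == 0L)) next
      if (length(req_masks) && any(bitwAnd(mask, req_masks) == 0L)) next
      members <- which(bitwAnd(mask, bits) != 0L)
      ok3 <- all(purrr::map_lgl(inner_sets, function(is3) {
        links_reachable(is3$from, is3$to, members, links)
      }))
      if (!ok3) next
      ex <- cands[members, ]
      lp <- solve_coverage_lp(ex, intervals, cfg$lp_lower_bound)
      if (lp$status != "optimal") next
      ncomb <- ncomb + 1L
      pen <- pair_feasibility_penalty(ex, info$classes, info$n_total, stats,
                                      intervals,
                                      links[members, members, drop = FALSE])
      score <- lp$objective + pen
      key <- as.numeric(t(ex[, c("start", "end")]))
      if (is.null(best) || score < best$score - 1e-9 ||
          (abs(score - best$score) <= 1e-9 &&
             (nrow(ex) < nrow(best$exons) ||
                (nrow(ex) == nrow(best$exons) &&
                   lex_cmp(key, best$key) < 0)))) {
        best <- list(exons = ex, score = score, key = key)
      }
    }
  }
  if (is.null(best)) {
    warning("region ", region$region_id,
            ": no feasible exon combination; emitting whole region")
    lp <- solve_coverage_lp(whole, intervals, cfg$lp_lower_bound)
    return(list(exons = whole, score = lp$objective,
                n_combinations = ncomb, fallback = TRUE))
  }
  list(exons = best$exons, score = best$score, n_combinations = ncomb,
       fallback = FALSE)
}

# above the enumeration cap, keep only read-evidenced candidates plus
# minimal completions so every splice site keeps at least one exon
restrict_candidates <- function(cands, pats, sites, region, cfg) {
  keep <- logical(nrow(cands))
  for (pat in pats) {
    sets <- pattern_required_sets(pat, cands)
    if (is.null(sets)) next
    for (s in sets) {
      if (length(s) == 1L) keep[s] <- TRUE  # uniquely required exon
    }
    # middle exons of spliced reads have both boundaries pinned
    if (nrow(pat$blocks) > 2L) {
      j <- pat$juncs
      for (m in 2:(nrow(pat$blocks) - 1L)) {
        keep[cands$start == j[m - 1L, 2L] & cands$end == j[m, 1L]] <- TRUE
      }
    }
  }
  for (s in seq_len(nrow(sites))) {
    touch <- if (sites$kind[s] == "donor") which(cands$end == sites$pos[s])
             else which(cands$start == sites$pos[s])
    if (!any(keep[touch]) && length(touch)) {
      # minimal completion: shortest exon touching the site
      w <- cands$end[touch] - cands$start[touch]
      keep[touch[which.min(w)]] <- TRUE
    }
  }
  message("region ", region$region_id, ": candidate list restricted from ",
          nrow(cands), " to ", sum(keep), " read-evidenced exons")
  out <- cands[keep, ]
  out$cand <- seq_len(nrow(out))
  out
}
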
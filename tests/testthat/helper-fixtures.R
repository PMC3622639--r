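# hand-built SAM fixtures ---------------------------------------------------

cigar_read_len <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIS=X]", cigar)[[1]]
  if (ops[1] == -1) return(0L)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIS=X]", cigar))[[1]]
  sum(as.integer(sub("[MIS=X]", "", toks)))
}

sam_rec <- function(qname, flag, pos1, cigar, contig = "chr1", mapq = 60,
                    rnext = "*", pnext = 0, tlen = 0, xs = NULL) {
  n <- max(1L, cigar_read_len(cigar))
  line <- paste(qname, flag, contig, pos1, mapq, cigar, rnext, pnext, tlen,
                strrep("A", n), "*", sep = "\t")
  if (!is.null(xs)) line <- paste0(line, "\tXS:A:", xs)
  line
}

write_test_sam <- function(records, path = tempfile(fileext = ".sam"),
                           contigs = c(chr1 = 1000000L)) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  writeLines(c(header, records), path)
  path
}

# in-memory read/junction/pair tables (bypassing SAM) ------------------------

toy_reads <- function(blocks_list, contig = "chr1", strand = "*") {
  tibble::tibble(
    read_id = sprintf("r%03d", seq_along(blocks_list)),
    contig = contig, strand = strand, mapq = 60L,
    is_paired = FALSE, is_first = FALSE,
    blocks = blocks_list,
    njunc = vapply(blocks_list, function(b) nrow(b) - 1L, integer(1)))
}

toy_junctions <- function(donors, acceptors, contig = "chr1",
                          strand = "+", support = 10L, max_anchor = 30L) {
  tibble::tibble(contig = contig, donor = as.integer(donors),
                 acceptor = as.integer(acceptors), strand = strand,
                 support = as.integer(support),
                 max_anchor = as.integer(max_anchor))
}

toy_region <- function(start, end, contig = "chr1", region_id = 1L,
                       strand_hint = "+") {
  tibble::tibble(region_id = region_id, contig = contig,
                 start = as.integer(start), end = as.integer(end),
                 strand_hint = strand_hint)
}

# tiling reads over a span (unspliced, fixed length, step 1 coverage `depth`)
tile_blocks <- function(start, end, len = 50L, by = 10L) {
  starts <- seq(start, max(start, end - len), by = by)
  lapply(starts, function(s) cbind(s, s + len))
}

# transcript tibble row from an exon matrix
toy_transcript <- function(exm, contig = "chr1", strand = "+",
                           transcript_id = "t1", gene_id = "g1") {
  tibble::tibble(transcript_id = transcript_id, gene_id = gene_id,
                 contig = contig, strand = strand, exons = list(exm),
                 introns = list(isocover:::blocks_to_introns(exm)),
                 n_exons = nrow(exm))
}

# independent LP oracle ------------------------------------------------------
# Rebuilds the subexon-coverage LP from scratch (different variable order,
# different linearisation bookkeeping) and solves it with SciPy's HiGHS
# solver through a python subprocess (batch interface, one call for many
# instances).

oracle_lp_build <- function(exons, intervals, lower_bound = 0) {
  cells <- list()
  for (i in seq_len(nrow(exons))) {
    for (j in exons$first_iv[i]:exons$last_iv[i]) {
      cells[[length(cells) + 1L]] <- c(i, j)
    }
  }
  nc <- length(cells)
  k <- nrow(intervals)
  cont <- list()
  for (i in seq_len(nrow(exons))) {
    jj <- exons$first_iv[i]:exons$last_iv[i]
    if (length(jj) > 1L) {
      for (m in seq_len(length(jj) - 1L)) {
        cont[[length(cont) + 1L]] <- c(i, jj[m], jj[m + 1L])
      }
    }
  }
  m <- length(cont)
  # variable order: eps_add, eps_cont, then c cells
  nv <- k + m + nc
  cpos <- function(cell) {
    k + m + which(vapply(cells, function(x) all(x == cell), logical(1)))
  }
  rows <- list(); rhs <- c()
  addrow <- function(v, b) {
    rows[[length(rows) + 1L]] <<- v; rhs <<- c(rhs, b)
  }
  for (j in seq_len(k)) {
    up <- rep(0, nv); lo <- rep(0, nv)
    for (ci in seq_along(cells)) {
      if (cells[[ci]][2] == j) {
        up[k + m + ci] <- 1; lo[k + m + ci] <- -1
      }
    }
    up[j] <- -1; lo[j] <- -1
    addrow(up, intervals$cbar[j])     # sum c - eps <= cbar
    addrow(lo, -intervals$cbar[j])    # -sum c - eps <= -cbar
  }
  for (r in seq_along(cont)) {
    a <- cpos(cont[[r]][c(1, 2)]); b <- cpos(cont[[r]][c(1, 3)])
    v1 <- rep(0, nv); v1[a] <- 1; v1[b] <- -1; v1[k + r] <- -1
    v2 <- -v1; v2[k + r] <- -1
    addrow(v1, 0); addrow(v2, 0)
  }
  A <- do.call(rbind, rows)
  Aeq <- matrix(0, 1, nv)
  for (ci in seq_along(cells)) {
    Aeq[1, k + m + ci] <- intervals$len[cells[[ci]][2]]
  }
  beq <- sum(intervals$cbar * intervals$len)
  cc <- c(rep(1, k + m), rep(0, nc))
  lb <- c(rep(0, k + m), rep(lower_bound, nc))
  list(cc = cc, A = A, b = rhs, Aeq = Aeq, beq = beq, lb = lb)
}

# solve a list of LPs (as built by oracle_lp_build) in one python call
oracle_lp_solve <- function(problems) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, infile, digits = NA)
  status <- system2("python",
                    c(testthat::test_path("lp-oracle.py"), infile,
                      outfile),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("LP oracle failed: ", paste(status, collapse = "\n"))
  }
  res <- jsonlite::read_json(outfile)
  vapply(res, function(x) {
    if (is.null(x$fun)) NA_real_ else as.numeric(x$fun)
  }, numeric(1))
}

oracle_lp_objective <- function(exons, intervals, lower_bound = 0) {
  v <- oracle_lp_solve(list(oracle_lp_build(exons, intervals,
                                            lower_bound)))
  if (is.na(v)) NULL else v
}

# random small LP instance (<= 6 subexon variables)
random_lp_instance <- function() {
  repeat {
    k <- sample(1:3, 1)
    intervals <- tibble::tibble(iv = seq_len(k),
                                start = (0:(k - 1)) * 100L,
                                end = (1:k) * 100L,
                                len = rep(100L, k),
                                cbar = round(stats::runif(k, 0.5, 20), 2))
    ne <- sample(1:3, 1)
    exons <- tibble::tibble(
      first_iv = vapply(seq_len(ne), function(i) sample(1:k, 1),
                        integer(1)))
    exons$last_iv <- vapply(exons$first_iv, function(f) {
      f + sample(0:(k - f), 1)
    }, integer(1))
    ncells <- sum(exons$last_iv - exons$first_iv + 1L)
    if (ncells <= 6L) {
      exons$start <- intervals$start[exons$first_iv]
      exons$end <- intervals$end[exons$last_iv]
      return(list(exons = exons, intervals = intervals))
    }
  }
}

# independent brute-force set-cover oracle -----------------------------------

oracle_min_cover <- function(sets, universe, weights = NULL) {
  n <- length(sets)
  if (is.null(weights)) weights <- rep(1, n)
  best_cost <- Inf; best <- NULL
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) != 0)
    if (all(universe %in% unlist(sets[idx]))) {
      cost <- sum(weights[idx])
      if (cost < best_cost) { best_cost <- cost; best <- idx }
    }
  }
  list(cost = best_cost, idx = best)
}

# build a constraint_graph object directly from cover sets
toy_cover_graph <- function(sets, universe, n_introns = NULL) {
  n <- length(sets)
  if (is.null(n_introns)) n_introns <- rep(1L, n)
  edges <- dplyr::bind_rows(lapply(seq_len(n), function(t) {
    if (length(sets[[t]]) == 0) return(NULL)
    tibble::tibble(constraint_id = sets[[t]], transcript_id = t)
  }))
  introns <- lapply(n_introns, function(m) {
    if (m == 0) matrix(integer(0), ncol = 2) else
      cbind(seq_len(m) * 100L, seq_len(m) * 100L + 50L)
  })
  structure(list(
    constraints = tibble::tibble(constraint_id = universe),
    transcripts = tibble::tibble(transcript_id = seq_len(n),
                                 introns = introns),
    edges = edges), class = "constraint_graph")
}

harmonic <- function(d) sum(1 / seq_len(max(1, d)))

# independent maximal-path oracle (plain recursive enumeration) --------------

oracle_maximal_paths <- function(node_ids, edges) {
  succ <- split(edges$to, edges$from)
  sources <- setdiff(node_ids, edges$to)
  walk <- function(v) {
    s <- succ[[as.character(v)]]
    if (is.null(s) || length(s) == 0) return(list(v))
    out <- list()
    for (w in s) {
      for (tail in walk(w)) out[[length(out) + 1L]] <- c(v, tail)
    }
    out
  }
  out <- list()
  for (s in sources) out <- c(out, walk(s))
  out
}

# random DAG as a splice-graph-compatible exon/junction pair
random_dag_fixture <- function(max_nodes = 8, p = 0.35) {
  n <- sample(2:max_nodes, 1)
  starts <- seq_len(n) * 1000L
  exons <- tibble::tibble(contig = "chr1", strand = "+",
                          start = starts, end = starts + 100L)
  ed <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        ed[[length(ed) + 1L]] <- c(exons$end[i], exons$start[j])
      }
    }
  }
  juncs <- if (length(ed)) {
    m <- do.call(rbind, ed)
    toy_junctions(m[, 1], m[, 2], support = sample(1:20, nrow(m),
                                                   replace = TRUE))
  } else {
    toy_junctions(integer(0), integer(0))
  }
  list(exons = exons, junctions = juncs)
}
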
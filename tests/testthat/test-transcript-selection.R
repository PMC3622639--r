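# shared fixture: one gene, exons E1 [0,200) (two intervals), E2 [500,600),
# E3 [900,1000); full and exon-skipping transcripts
ts_intervals <- function() {
  tibble::tibble(interval_id = 1:4, region_id = c(1L, 1L, 2L, 3L),
                 contig = "chr1",
                 start = c(0L, 100L, 500L, 900L),
                 end = c(100L, 200L, 600L, 1000L),
                 len = c(100L, 100L, 100L, 100L), cbar = 10)
}
ts_full <- function() {
  toy_transcript(cbind(c(0L, 500L, 900L), c(200L, 600L, 1000L)),
                 transcript_id = "full")
}
ts_skip <- function() {
  toy_transcript(cbind(c(0L, 900L), c(200L, 1000L)),
                 transcript_id = "skip")
}

test_that("identical reads collapse into one constraint with multiplicity", {
  iv <- ts_intervals()
  reads <- toy_reads(rep(list(cbind(20L, 70L)), 100))
  aln <- list(reads = reads,
              pairs = tibble::tibble(read_id = character(),
                                     contig = character(),
                                     strand = character(),
                                     left_blocks = list(),
                                     right_blocks = list(),
                                     left_njunc = integer(),
                                     right_njunc = integer(),
                                     left_start = integer(),
                                     right_end = integer()))
  cons <- derive_constraints(aln, iv)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$multiplicity, 100L)
  expect_equal(cons$mates[[1]][[1]]$ivs, 1L)
})

test_that("spliced reads, pairs, and out-of-region reads derive correctly", {
  iv <- ts_intervals()
  reads <- toy_reads(list(
    cbind(c(150L, 500L), c(200L, 540L)),  # spliced over intron 200-500
    cbind(3000L, 3050L)))                 # outside all intervals
  pairs <- tibble::tibble(
    read_id = "p1", contig = "chr1", strand = "*",
    left_blocks = list(cbind(20L, 60L)),
    right_blocks = list(cbind(920L, 960L)),
    left_njunc = 0L, right_njunc = 0L,
    left_start = 20L, right_end = 960L)
  aln <- list(reads = reads, pairs = pairs)
  cons <- derive_constraints(aln, iv)
  expect_equal(attr(cons, "n_ignored"), 1L)
  expect_equal(nrow(cons), 2L)
  spl <- cons[vapply(cons$pair_iv, is.null, logical(1)), ]
  expect_equal(spl$mates[[1]][[1]]$ivs, c(2L, 3L))
  expect_equal(spl$mates[[1]][[1]]$juncs, cbind(200L, 500L),
               ignore_attr = TRUE)
  pc <- cons[!vapply(cons$pair_iv, is.null, logical(1)), ]
  expect_equal(pc$pair_iv[[1]], c(1L, 4L))
})

test_that("constraint satisfaction follows interval runs and intron chains", {
  iv <- ts_intervals()
  full <- ts_full(); skip <- ts_skip()
  aln <- list(reads = toy_reads(list(
    cbind(20L, 70L),                       # inside iv1
    cbind(c(150L, 500L), c(200L, 540L)),   # junction 200-500
    cbind(c(150L, 900L), c(200L, 940L)))), # junction 200-900 (skip)
    pairs = tibble::tibble(read_id = character(), contig = character(),
                           strand = character(), left_blocks = list(),
                           right_blocks = list(), left_njunc = integer(),
                           right_njunc = integer(), left_start = integer(),
                           right_end = integer()))
  cons <- derive_constraints(aln, iv)
  in1 <- cons[vapply(cons$mates, function(m) identical(m[[1]]$ivs, 1L),
                     logical(1)), ]
  j25 <- cons[vapply(cons$mates,
                     function(m) identical(m[[1]]$ivs, c(2L, 3L)),
                     logical(1)), ]
  j29 <- cons[vapply(cons$mates,
                     function(m) identical(m[[1]]$ivs, c(2L, 4L)),
                     logical(1)), ]
  expect_true(satisfies_constraint(full, in1, iv))
  expect_true(satisfies_constraint(skip, in1, iv))
  expect_true(satisfies_constraint(full, j25, iv))
  expect_false(satisfies_constraint(skip, j25, iv))   # iv3 not on skip
  expect_false(satisfies_constraint(full, j29, iv))   # extra intron inside
  expect_true(satisfies_constraint(skip, j29, iv))
})

test_that("pair constraints respect the fragment-length window", {
  iv <- ts_intervals()
  full <- ts_full()
  con <- tibble::tibble(
    constraint_id = 1L, contig = "chr1", strand = "*",
    mates = list(list(list(ivs = 1L, juncs = isocover:::empty_mat2()),
                      list(ivs = 4L, juncs = isocover:::empty_mat2()))),
    pair_iv = list(c(1L, 4L)), multiplicity = 1L)
  wide <- estimate_fragment_stats(NULL, override = c(250, 25))
  narrow <- estimate_fragment_stats(NULL, override = c(150, 10))
  # transcript-implied range over full: [202, 400]
  expect_true(satisfies_constraint(full, con, iv, wide))    # window 200-300
  expect_false(satisfies_constraint(full, con, iv, narrow)) # window 130-170
  # without fragment statistics the window check is skipped
  expect_true(satisfies_constraint(full, con, iv, NULL))
})

test_that("unsatisfiable constraints are pruned", {
  g <- toy_cover_graph(sets = list(c(1L, 2L, 3L)), universe = 1:4)
  pruned <- prune_unsatisfiable(g)
  expect_equal(nrow(pruned$constraints), 3L)
  expect_equal(attr(pruned, "n_removed"), 1L)

  g2 <- toy_cover_graph(sets = list(1:4), universe = 1:4)
  expect_equal(nrow(prune_unsatisfiable(g2)$constraints), 4L)
})

test_that("greedy cover picks dominating transcripts", {
  g <- toy_cover_graph(sets = list(c(1L, 2L, 3L), 1L), universe = 1:3)
  expect_equal(greedy_set_cover(g), 1L)

  g2 <- toy_cover_graph(sets = list(1:5), universe = 1:5)
  expect_equal(greedy_set_cover(g2), 1L)
})

test_that("weighted cover uses the cost-effectiveness rule", {
  g <- toy_cover_graph(sets = list(1:4, 1:4), universe = 1:4)
  w <- c("1" = 1.8, "2" = 1.0)
  expect_equal(weighted_greedy_set_cover(g, w), 2L)
  # all weights equal reduces to the unweighted result
  expect_equal(weighted_greedy_set_cover(g, c("1" = 1, "2" = 1)),
               greedy_set_cover(g))
})

test_that("greedy cover is valid, near-optimal, and deterministic", {
  set.seed(202)
  for (rep in 1:40) {
    nt <- sample(2:10, 1); nc <- sample(2:12, 1)
    sets <- lapply(seq_len(nt), function(i) {
      s <- which(runif(nc) < runif(1, 0.2, 0.8))
      if (length(s) == 0) s <- sample.int(nc, 1)
      as.integer(s)
    })
    universe <- sort(unique(unlist(sets)))
    g <- toy_cover_graph(sets, universe)
    w <- round(runif(nt, 1, 2), 2); names(w) <- seq_len(nt)

    s_un <- greedy_set_cover(g)
    expect_true(all(universe %in% unlist(sets[s_un])))  # valid cover
    opt <- oracle_min_cover(sets, universe)
    d <- max(lengths(sets))
    expect_lte(length(s_un), harmonic(d) * length(opt$idx) + 1e-9)

    s_w <- weighted_greedy_set_cover(g, w)
    expect_true(all(universe %in% unlist(sets[s_w])))
    opt_w <- oracle_min_cover(sets, universe, w)
    expect_lte(sum(w[s_w]), harmonic(d) * opt_w$cost + 1e-9)

    ones <- stats::setNames(rep(1, nt), seq_len(nt))
    expect_identical(weighted_greedy_set_cover(g, ones), s_un)
    expect_identical(greedy_set_cover(g), s_un)  # determinism
  }
})

test_that("annotation intron pairs are collected as a set", {
  tx <- dplyr::bind_rows(
    toy_transcript(cbind(c(0L, 300L, 600L), c(100L, 400L, 700L)),
                   transcript_id = "three_exon"),
    toy_transcript(cbind(c(2000L, 2300L), c(2100L, 2400L)),
                   transcript_id = "two_exon", gene_id = "g2"),
    toy_transcript(cbind(c(0L, 300L, 600L, 900L), c(100L, 400L, 700L,
                                                    950L)),
                   transcript_id = "shares_pair", gene_id = "g3"))
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(tx, gtf)
  ev <- load_evidence_intron_pairs(gtf)
  # three_exon contributes 1 pair; two_exon none; shares_pair repeats the
  # first pair and adds one more
  expect_equal(length(ev), 2L)
})

test_that("transcript weights follow 1 + lambda * (1 - evidence fraction)", {
  ex6 <- cbind(seq(0L, 2500L, by = 500L), seq(100L, 2600L, by = 500L))
  t6 <- toy_transcript(ex6)   # 5 introns -> 4 consecutive pairs
  keys <- isocover:::intron_pair_keys(t6$introns[[1]], "chr1", "+")
  expect_equal(length(keys), 4L)

  all_ev <- transcript_weights(t6, keys, lambda = 1)
  expect_equal(all_ev$weight, 1.0)
  none <- transcript_weights(t6, character(0), lambda = 1)
  expect_equal(none$weight, 2.0)
  half <- transcript_weights(t6, keys[1:2], lambda = 1)
  expect_equal(half$weight, 1.5)

  mono <- toy_transcript(cbind(0L, 500L))  # no introns: weight 1
  expect_equal(transcript_weights(mono, character(0))$weight, 1.0)
})
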
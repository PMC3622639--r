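test_that("boundaries partition a region into coverage-annotated intervals", {
  reg <- toy_region(0, 500)
  reads <- toy_reads(list(cbind(0L, 50L)))
  iv <- partition_intervals(reg, c(100, 200, 300, 400), reads)
  expect_equal(nrow(iv), 5L)
  expect_equal(iv$start, c(0L, 100L, 200L, 300L, 400L))
  expect_equal(iv$end, c(100L, 200L, 300L, 400L, 500L))
  expect_equal(sum(iv$len), 500L)

  one <- partition_intervals(reg, integer(0), reads)
  expect_equal(nrow(one), 1L)

  # one 50-base block over a 100-base interval: mean coverage 0.5
  iv2 <- partition_intervals(toy_region(0, 100), integer(0), reads)
  expect_equal(iv2$cbar, 0.5)
})

test_that("candidate exons pair acceptor-side lefts with donor-side rights", {
  # five intervals, alternating donor/acceptor boundaries: 6 possible exons
  reg <- toy_region(0, 500)
  iv <- partition_intervals(reg, c(100, 200, 300, 400), toy_reads(list()))
  sites <- tibble::tibble(pos = c(100L, 200L, 300L, 400L),
                          kind = c("donor", "acceptor", "donor",
                                   "acceptor"),
                          strand = "+")
  cands <- enumerate_candidate_exons(reg, iv, sites)
  expect_equal(nrow(cands), 6L)
  expect_true(all(cands$start < cands$end))
  expect_setequal(
    paste(cands$start, cands$end),
    c("0 100", "0 300", "0 500", "200 300", "200 500", "400 500"))

  # no boundaries: exactly the whole-region exon
  iv0 <- partition_intervals(reg, integer(0), toy_reads(list()))
  none <- tibble::tibble(pos = integer(0), kind = character(0),
                         strand = character(0))
  expect_equal(nrow(enumerate_candidate_exons(reg, iv0, none)), 1L)
})

test_that("feasibility conditions reject bad combinations with reasons", {
  reg <- toy_region(0, 300)
  iv <- partition_intervals(reg, c(100, 200), toy_reads(list()))
  sites <- tibble::tibble(pos = c(100L, 200L),
                          kind = c("donor", "acceptor"), strand = "+")
  cands <- enumerate_candidate_exons(reg, iv, sites)
  c_short <- cands$cand[cands$start == 0 & cands$end == 100]
  c_full <- cands$cand[cands$start == 0 & cands$end == 300]
  c_right <- cands$cand[cands$start == 200 & cands$end == 300]
  juncs <- toy_junctions(100, 200)

  # condition 1: no member ends at the donor
  r <- is_feasible_combination(c(c_full, c_right), cands, reg, iv,
                               toy_reads(list()), strand = "+")
  expect_false(as.logical(r))
  expect_equal(attr(r, "reason"), "uncovered_splice_site")

  # condition 2: unspliced read across the donor needs a spanning exon
  crossing <- toy_reads(list(cbind(90L, 110L)))
  r2 <- is_feasible_combination(c(c_short, c_right), cands, reg, iv,
                                crossing, strand = "+")
  expect_false(as.logical(r2))
  expect_equal(attr(r2, "reason"), "incompatible_read")
  expect_true(is_feasible_combination(c(c_short, c_full, c_right), cands,
                                      reg, iv, crossing, strand = "+"))

  # spliced read over the junction is compatible with short + right exons
  spliced <- toy_reads(list(cbind(c(80L, 200L), c(100L, 220L))))
  expect_true(is_feasible_combination(c(c_short, c_right), cands, reg, iv,
                                      spliced, junctions = juncs,
                                      strand = "+"))

  # condition 3: junction-linked mates are compatible, unlinked are not
  pairs <- tibble::tibble(
    read_id = "p1", contig = "chr1", strand = "*",
    left_blocks = list(cbind(50L, 90L)),
    right_blocks = list(cbind(210L, 250L)),
    left_njunc = 0L, right_njunc = 0L,
    left_start = 50L, right_end = 250L)
  expect_true(is_feasible_combination(c(c_short, c_right), cands, reg, iv,
                                      toy_reads(list()), pairs = pairs,
                                      junctions = juncs, strand = "+"))
  r3 <- is_feasible_combination(c(c_short, c_right), cands, reg, iv,
                                toy_reads(list()), pairs = pairs,
                                junctions = NULL, strand = "+")
  expect_false(as.logical(r3))
  expect_equal(attr(r3, "reason"), "incompatible_pair")
})

test_that("the coverage LP solves exactly determined systems", {
  iv <- tibble::tibble(iv = 1L, start = 0L, end = 100L, len = 100L,
                       cbar = 7)
  ex <- tibble::tibble(cand = 1L, start = 0L, end = 100L,
                       first_iv = 1L, last_iv = 1L)
  sol <- solve_coverage_lp(ex, iv, lower_bound = 1)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0, tolerance = 1e-8)
  expect_equal(sol$c$coverage, 7, tolerance = 1e-8)
})

test_that("the LP objective measures unavoidable slack", {
  iv <- tibble::tibble(iv = 1:2, start = c(0L, 100L), end = c(100L, 200L),
                       len = c(100L, 100L), cbar = c(8, 8))
  ex <- tibble::tibble(cand = 1:2, start = 0L, end = 200L,
                       first_iv = 1L, last_iv = 2L)
  sol <- solve_coverage_lp(ex, iv, lower_bound = 1)
  expect_equal(sol$objective, 0, tolerance = 1e-8)

  iv$cbar <- c(8, 6)
  sol2 <- solve_coverage_lp(ex, iv, lower_bound = 1)
  oracle <- oracle_lp_objective(ex, iv, lower_bound = 1)
  expect_equal(sol2$objective, oracle, tolerance = 1e-6)
  expect_equal(sol2$objective, 2, tolerance = 1e-6)
})

test_that("LP objective is translation invariant and scales linearly", {
  set.seed(7)
  for (rep in 1:10) {
    inst <- random_lp_instance()
    s1 <- solve_coverage_lp(inst$exons, inst$intervals, lower_bound = 0)
    shifted <- inst$intervals
    shifted$start <- shifted$start + 10000L
    shifted$end <- shifted$end + 10000L
    s2 <- solve_coverage_lp(inst$exons, shifted, lower_bound = 0)
    expect_equal(s1$objective, s2$objective, tolerance = 1e-8)

    scaled <- inst$intervals
    scaled$cbar <- scaled$cbar * 3
    s3 <- solve_coverage_lp(inst$exons, scaled, lower_bound = 0)
    expect_equal(s3$objective, 3 * s1$objective, tolerance = 1e-6)
  }
})

test_that("infeasible lower bound falls back to zero, then reports", {
  # conservation (total mass 0.5 * 100) conflicts with c >= 1
  iv <- tibble::tibble(iv = 1L, start = 0L, end = 100L, len = 100L,
                       cbar = 0.5)
  ex <- tibble::tibble(cand = 1:2, start = 0L, end = 100L,
                       first_iv = 1L, last_iv = 1L)
  sol <- solve_coverage_lp(ex, iv, lower_bound = 1)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$lower_bound_used, 0)
})

test_that("the pair penalty charges unexplainable pair classes", {
  win_stats <- estimate_fragment_stats(NULL, override = c(250, 25))
  iv <- tibble::tibble(iv = 1:3,
                       start = c(0L, 100L, 1300L),
                       end = c(100L, 200L, 1400L),
                       len = c(100L, 100L, 100L), cbar = 10)
  exons_near <- tibble::tibble(cand = 1:2,
                               start = c(0L, 1000L), end = c(100L, 1100L),
                               first_iv = c(1L, 3L), last_iv = c(1L, 3L))
  # near geometry: achievable range overlaps the window -> no penalty
  iv_near <- iv
  iv_near$start[3] <- 1000L; iv_near$end[3] <- 1100L
  links <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2, byrow = TRUE)
  cls <- tibble::tibble(iv_i = 1L, iv_j = 3L, n = 30L)
  expect_equal(pair_feasibility_penalty(exons_near, cls, 100L, win_stats,
                                        iv_near, links), 0)

  # distant geometry: minimal distance 302 > 300 -> class is charged
  exons_far <- tibble::tibble(cand = 1:2,
                              start = c(0L, 1000L), end = c(100L, 1400L),
                              first_iv = c(1L, 3L), last_iv = c(1L, 3L))
  expect_equal(pair_feasibility_penalty(exons_far, cls, 100L, win_stats,
                                        iv, links), 0.30)

  # two infeasible classes of 10 and 5 out of 100 pairs
  cls2 <- tibble::tibble(iv_i = c(1L, 1L), iv_j = c(3L, 3L),
                         n = c(10L, 5L))
  expect_equal(pair_feasibility_penalty(exons_far, cls2, 100L, win_stats,
                                        iv, links), 0.15)

  # single-end mode
  expect_equal(pair_feasibility_penalty(exons_far, cls, 100L, NULL, iv,
                                        links), 0)
})

test_that("exon selection returns forced combinations and prefers fewer exons", {
  # donor at 150 with reads crossing it: the only feasible combination is
  # {short exon, whole-region exon}
  reg <- toy_region(0, 300)
  reads <- toy_reads(c(tile_blocks(0, 300), tile_blocks(0, 150)))
  sites <- tibble::tibble(pos = 150L, kind = "donor", strand = "+")
  iv <- partition_intervals(reg, sites$pos, reads)
  sel <- select_exon_set(reg, iv, sites, reads,
                         junctions = toy_junctions(150, 400))
  expect_equal(sort(paste(sel$exons$start, sel$exons$end)),
               c("0 150", "0 300"))

  # donor and acceptor at 100, no read crossing it: the zero-slack
  # 2-exon and 3-exon combinations tie; fewest exons wins
  reg2 <- toy_region(0, 200)
  reads2 <- toy_reads(c(tile_blocks(10, 90, len = 40L),
                        tile_blocks(110, 190, len = 40L)))
  sites2 <- tibble::tibble(pos = c(100L, 100L),
                           kind = c("donor", "acceptor"), strand = "+")
  iv2 <- partition_intervals(reg2, 100L, reads2)
  sel2 <- select_exon_set(reg2, iv2, sites2, reads2,
                          junctions = toy_junctions(c(100, 50),
                                                    c(400, 100)))
  expect_equal(nrow(sel2$exons), 2L)
  expect_equal(sort(paste(sel2$exons$start, sel2$exons$end)),
               c("0 100", "100 200"))
})

test_that("a region with no splice sites yields its single exon", {
  reg <- toy_region(0, 200)
  reads <- toy_reads(tile_blocks(0, 200))
  iv <- partition_intervals(reg, integer(0), reads)
  none <- tibble::tibble(pos = integer(0), kind = character(0),
                         strand = character(0))
  sel <- select_exon_set(reg, iv, none, reads)
  expect_equal(nrow(sel$exons), 1L)
  expect_equal(sel$exons$start, 0L)
  expect_equal(sel$exons$end, 200L)
})
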
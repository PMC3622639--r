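# hand-built two-isoform gene (skipped exon) with known truth
skip_gene_models <- function() {
  e1 <- c(1000L, 1200L); e2 <- c(1500L, 1700L); e3 <- c(2000L, 2200L)
  full <- rbind(e1, e2, e3)
  skip <- rbind(e1, e3)
  tibble::tibble(
    gene_id = "g001", contig = "chr1", strand = "+",
    isoforms = list(tibble::tibble(
      transcript_id = c("g001.t1", "g001.t2"),
      exons = list(full, skip), weight = c(0.5, 0.5))))
}

test_that("a skipped-exon gene is reassembled exactly from its reads", {
  models <- skip_gene_models()
  sam <- tempfile(fileext = ".sam"); gtf <- tempfile(fileext = ".gtf")
  simulate_alignments(models, sam, gtf, depth = 30, seed = 21)
  fit <- assemble_transcripts(sam)
  expect_equal(nrow(fit$transcripts), 2L)
  got <- sort(purrr::map_chr(fit$transcripts$introns, isocover:::chain_key))
  want <- sort(purrr::map_chr(
    isocover:::models_to_transcripts(models)$introns,
    isocover:::chain_key))
  expect_equal(got, want)
  # chosen exons: splice-site boundaries are exact; the outer terminal
  # edges are coverage boundaries and may fall a few bases inside the
  # true transcript ends
  ex <- fit$exons[order(fit$exons$start), ]
  expect_equal(nrow(ex), 3L)
  expect_lt(abs(ex$start[1] - 1000L), 20L)
  expect_equal(ex$end[1], 1200L)
  expect_equal(c(ex$start[2], ex$end[2]), c(1500L, 1700L))
  expect_equal(ex$start[3], 2000L)
  expect_lt(abs(ex$end[3] - 2200L), 20L)
})

test_that("assembly output is deterministic and GTF round-trips", {
  sim <- simulate_rnaseq(tempfile(), n_genes = 4, seed = 31, depth = 40)
  out1 <- tempfile(fileext = ".gtf"); out2 <- tempfile(fileext = ".gtf")
  fit1 <- assemble_transcripts(sim$sam)
  write_gtf(fit1, out1)
  fit2 <- assemble_transcripts(sim$sam)
  write_gtf(fit2, out2)
  expect_identical(readLines(out1), readLines(out2))

  back <- read_gtf_transcripts(out1)
  expect_equal(nrow(back), nrow(fit1$transcripts))
  expect_setequal(purrr::map_chr(back$introns, isocover:::chain_key),
                  purrr::map_chr(fit1$transcripts$introns,
                                 isocover:::chain_key))
  expect_setequal(purrr::map_chr(back$exons, isocover:::chain_key),
                  purrr::map_chr(fit1$transcripts$exons,
                                 isocover:::chain_key))
})

test_that("single-end data assembles without fragment statistics", {
  sim <- simulate_rnaseq(tempfile(), n_genes = 3, seed = 41, depth = 40,
                         paired = FALSE)
  fit <- assemble_transcripts(sim$sam)
  expect_null(fit$stats)
  rep <- accuracy_report(fit$transcripts, sim$truth, v = 0,
                         multi_exon_only = TRUE)
  expect_gte(rep$transcript$recall, 0.9)
})

test_that("weighted selection with truth evidence matches at least as many", {
  sim <- simulate_rnaseq(tempfile(), n_genes = 6, seed = 51, depth = 50)
  fit0 <- assemble_transcripts(sim$sam)
  fitw <- assemble_transcripts(sim$sam, annotation = sim$gtf,
                               weighted = TRUE)
  r0 <- accuracy_report(fit0$transcripts, sim$truth, v = 0,
                        multi_exon_only = TRUE)
  rw <- accuracy_report(fitw$transcripts, sim$truth, v = 0,
                        multi_exon_only = TRUE)
  expect_gte(rw$transcript$k, r0$transcript$k)
})

test_that("annotation evidence breaks selection ties toward known forms", {
  # two transcripts cover the same constraints; the annotated one must win
  g <- toy_cover_graph(sets = list(1:3, 1:3), universe = 1:3,
                       n_introns = c(2L, 2L))
  w <- c("1" = 2.0, "2" = 1.0)   # transcript 2 fully annotation-supported
  expect_equal(weighted_greedy_set_cover(g, w), 2L)
  expect_equal(greedy_set_cover(g), 1L)  # unweighted: id order
})

test_that("the tidy accessors summarise a fit", {
  sim <- simulate_rnaseq(tempfile(), n_genes = 2, seed = 61, depth = 30)
  fit <- assemble_transcripts(sim$sam)
  td <- tidy(fit)
  expect_true(all(c("transcript_id", "gene_id", "n_exons",
                    "intron_chain") %in% names(td)))
  expect_equal(nrow(td), nrow(fit$transcripts))
  g <- glance(fit)
  expect_equal(g$n_transcripts, nrow(fit$transcripts))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the command-line interface wires the three subcommands", {
  cli <- system.file("cli", "isocover.R", package = "isocover")
  skip_if(cli == "", "CLI script not found")
  d <- tempfile(); dir.create(d)
  pre <- file.path(d, "sim")
  r1 <- system2("Rscript", c(cli, "simulate", "--out-prefix", pre,
                             "--seed", "2", "--genes", "2",
                             "--depth", "30"),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(paste0(pre, ".sam")))
  out <- file.path(d, "out.gtf")
  r2 <- system2("Rscript", c(cli, "assemble", "--alignments",
                             paste0(pre, ".sam"), "--output", out),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  expect_gt(length(readLines(out)), 0L)
  r3 <- system2("Rscript", c(cli, "evaluate", "--pred", out, "--ref",
                             paste0(pre, ".gtf"), "--multi-exon-only",
                             "--out", file.path(d, "acc")),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(d, "acc.summary.tsv")))
  expect_true(file.exists(file.path(d, "acc.json")))
  smry <- utils::read.delim(file.path(d, "acc.summary.tsv"))
  expect_equal(smry$tx_recall, 1)

  # unreadable input exits non-zero
  r4 <- suppressWarnings(
    system2("Rscript", c(cli, "assemble", "--alignments", "missing.sam",
                         "--output", out), stdout = TRUE, stderr = TRUE))
  expect_true(!is.null(attr(r4, "status")) && attr(r4, "status") != 0)
})
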
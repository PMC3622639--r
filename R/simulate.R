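#' Generate multi-isoform gene models on a toy genome
#'
#' Builds deterministic gene models for simulation: each gene has a base
#' isoform using all its exons, and up to two alternative isoforms produced
#' by one of the classic local splicing events (skipped exon, alternative
#' donor, alternative acceptor, alternative terminal exon). All alternative
#' events of a gene act at a single variable site, so the isoform set of a
#' gene equals the set of maximal paths through its splice graph -- the
#' regime in which a path-enumerating assembler can recover the truth
#' exactly. Isoforms within a gene always differ by at least one intron.
#'
#' @param n_genes Number of genes.
#' @param seed Random seed; output is deterministic given the seed.
#' @param exon_len,intron_len Length ranges (nt), inclusive.
#' @param n_exons Range of exons per gene (>= 3 recommended so internal
#'   events are possible).
#' @param isoforms_per_gene Range of isoforms per gene (1 to 3).
#' @param contig Contig name.
#' @param gene_gap Intergenic distance (nt).
#' @param origin Genomic start of the first gene (0-based).
#' @return A tibble with one row per gene: `gene_id`, `contig`, `strand`,
#'   `isoforms` (list of tibbles `transcript_id`, `exons`, `weight`).
#' @export
make_gene_models <- function(n_genes = 20, seed = 1,
                             exon_len = c(100, 300),
                             intron_len = c(100, 500),
                             n_exons = c(4, 7),
                             isoforms_per_gene = c(1, 3),
                             contig = "chr1", gene_gap = 3000,
                             origin = 1000) {
  stopifnot(exon_len[1] >= 50, intron_len[1] >= 50, n_exons[1] >= 3,
            isoforms_per_gene[1] >= 1, isoforms_per_gene[2] <= 3)
  set.seed(seed)
  pos <- origin
  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    ne <- resample(n_exons[1]:n_exons[2], 1L)
    elens <- resample(exon_len[1]:exon_len[2], ne, replace = TRUE)
    ilens <- resample(intron_len[1]:intron_len[2], ne - 1L, replace = TRUE)
    starts <- pos + cumsum(c(0L, elens[-ne] + ilens))
    exons <- cbind(starts, starts + elens)
    strand <- if (g %% 2L == 1L) "+" else "-"
    k <- resample(isoforms_per_gene[1]:isoforms_per_gene[2], 1L)
    isos <- alternative_isoforms(exons, k, exon_len, intron_len)
    w <- stats::runif(length(isos), 0.5, 1.5)
    w <- w / sum(w)
    gene_id <- sprintf("g%03d", g)
    iso_tb <- tibble::tibble(
      transcript_id = sprintf("%s.t%d", gene_id, seq_along(isos)),
      exons = isos, weight = w)
    genes[[g]] <- tibble::tibble(gene_id = gene_id, contig = contig,
                                 strand = strand, isoforms = list(iso_tb))
    pos <- as.integer(max(purrr::map_int(isos,
                                         ~ max(.x[, 2L]))) + gene_gap)
  }
  dplyr::bind_rows(genes)
}

# base isoform plus up to two variants, all at one variable site so the
# splice graph's maximal paths coincide with the isoform set
alternative_isoforms <- function(exons, k, exon_len, intron_len) {
  ne <- nrow(exons)
  isos <- list(exons)
  if (k == 1L) return(isos)
  v <- resample(2:(ne - 1L), 1L)  # variable internal exon
  delta <- function() {
    resample(40:min(80, exons[v, 2] - exons[v, 1] - 40), 1L)
  }
  variants <- list(
    skip = function() exons[-v, , drop = FALSE],
    alt_donor = function() {
      m <- exons; m[v, 2L] <- m[v, 2L] - delta(); m
    },
    alt_acceptor = function() {
      m <- exons; m[v, 1L] <- m[v, 1L] + delta(); m
    },
    alt_last = function() {
      gap <- resample(intron_len[1]:intron_len[2], 1L)
      len <- resample(exon_len[1]:exon_len[2], 1L)
      s <- exons[ne, 2L] + gap
      rbind(exons[-ne, , drop = FALSE], c(s, s + len))
    })
  if (k == 2L) {
    ev <- resample(names(variants), 1L)
    isos[[2L]] <- variants[[ev]]()
  } else {
    # two mutually exclusive events at the same internal site; pairing the
    # exon skip with one alternative-splice-site event keeps every isoform
    # identifiable from junction-bearing reads alone
    evs <- c("skip", resample(c("alt_donor", "alt_acceptor"), 1L))
    isos[[2L]] <- variants[[evs[1L]]]()
    isos[[3L]] <- variants[[evs[2L]]]()
  }
  isos
}

#' Simulate spliced read alignments with known truth
#'
#' Fragments are sampled uniformly along each isoform in proportion to its
#' weight; fragment lengths are Gaussian (truncated to the feasible range);
#' reads are projected back to the genome, producing gapped CIGAR strings
#' across introns. No sequencing errors are introduced. Spliced records
#' carry an `XS` strand tag, paired records proper-pair flags. The output
#' SAM is coordinate-sorted and deterministic given the seed.
#'
#' @param models Gene models from [make_gene_models()].
#' @param sam,gtf Output paths for the alignments and the truth annotation.
#' @param depth Target per-base read coverage per gene (all isoforms
#'   combined).
#' @param read_len Read length (nt).
#' @param paired Simulate read pairs (`TRUE`) or single-end reads.
#' @param frag_mean,frag_sd Fragment length distribution (nt), paired mode.
#' @param seed Random seed.
#' @return Invisibly, a list with `sam`, `gtf` and the truth transcript
#'   tibble.
#' @export
simulate_alignments <- function(models, sam, gtf, depth = 50,
                                read_len = 75, paired = TRUE,
                                frag_mean = 250, frag_sd = 25, seed = 1) {
  records <- list()
  for (g in seq_len(nrow(models))) {
    set.seed((seed * 1000L + g) %% .Machine$integer.max)
    iso <- models$isoforms[[g]]
    strand <- models$strand[g]
    contig <- models$contig[g]
    for (i in seq_len(nrow(iso))) {
      ex <- iso$exons[[i]]
      tlen <- sum(ex[, 2L] - ex[, 1L])
      if (tlen < read_len) next
      n_frag <- round(depth * iso$weight[i] * tlen /
                        (read_len * (if (paired) 2 else 1)))
      if (n_frag == 0L) next
      qpre <- paste0(iso$transcript_id[i], ".f")
      for (f in seq_len(n_frag)) {
        qname <- paste0(qpre, f)
        if (paired) {
          flen <- draw_fragment(frag_mean, frag_sd, read_len, tlen)
          s <- sample.int(tlen - flen + 1L, 1L) - 1L
          lb <- project_to_genome(ex, s, s + read_len)
          rb <- project_to_genome(ex, s + flen - read_len, s + flen)
          records[[length(records) + 1L]] <-
            sam_pair(qname, contig, strand, lb, rb, read_len)
        } else {
          s <- sample.int(tlen - read_len + 1L, 1L) - 1L
          b <- project_to_genome(ex, s, s + read_len)
          records[[length(records) + 1L]] <-
            sam_single(qname, contig, strand, b, read_len)
        }
      }
    }
  }
  recs <- dplyr::bind_rows(records)
  if (nrow(recs) > 0L) {
    recs <- dplyr::arrange(recs, .data$contig, .data$pos)
  } else {
    recs <- tibble::tibble(contig = character(), pos = integer(),
                           line = character())
  }
  contigs <- unique(models$contig)
  maxend <- purrr::map_dbl(contigs, function(ct) {
    rows <- models[models$contig == ct, ]
    max(purrr::map_dbl(rows$isoforms,
                       ~ max(purrr::map_dbl(.x$exons, ~ max(.x[, 2L])))))
  })
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs,
                      as.integer(maxend + 1000)))
  writeLines(c(header, recs$line), sam)
  truth <- models_to_transcripts(models)
  write_gtf(truth, gtf, source = "simulated")
  invisible(list(sam = sam, gtf = gtf, truth = truth))
}

# truncated-normal fragment length in [read_len, tlen] (rejection sampling
# with a deterministic clamp fallback for very short transcripts)
draw_fragment <- function(mean, sd, read_len, tlen) {
  lo <- read_len; hi <- tlen
  for (i in 1:50) {
    x <- round(stats::rnorm(1, mean, sd))
    if (x >= lo && x <= hi) return(as.integer(x))
  }
  as.integer(max(lo, min(hi, round(mean))))
}

# map a transcript-coordinate interval [s, e) onto genomic blocks
project_to_genome <- function(exons, s, e) {
  lens <- exons[, 2L] - exons[, 1L]
  cum <- cumsum(c(0L, lens))
  out <- NULL
  for (r in seq_len(nrow(exons))) {
    a <- max(s, cum[r]); b <- min(e, cum[r + 1L])
    if (a < b) {
      out <- rbind(out, c(exons[r, 1L] + (a - cum[r]),
                          exons[r, 1L] + (b - cum[r])))
    }
  }
  out
}

blocks_to_cigar <- function(blocks) {
  k <- nrow(blocks)
  parts <- character(0)
  for (r in seq_len(k)) {
    parts <- c(parts, paste0(as.integer(blocks[r, 2L] - blocks[r, 1L]),
                             "M"))
    if (r < k) {
      parts <- c(parts,
                 paste0(as.integer(blocks[r + 1L, 1L] - blocks[r, 2L]),
                        "N"))
    }
  }
  paste(parts, collapse = "")
}

sam_fields <- function(qname, flag, contig, blocks, read_len, strand,
                       rnext = "*", pnext = 0L, tlen = 0L) {
  spliced <- nrow(blocks) > 1L
  xs <- if (spliced) paste0("\tXS:A:", strand) else ""
  pos1 <- as.integer(blocks[1L, 1L]) + 1L
  tibble::tibble(
    contig = contig, pos = pos1,
    line = paste0(paste(qname, flag, contig, pos1, 60L,
                        blocks_to_cigar(blocks), rnext,
                        as.integer(pnext), as.integer(tlen),
                        strrep("A", read_len), "*", sep = "\t"), xs))
}

sam_single <- function(qname, contig, strand, blocks, read_len) {
  sam_fields(qname, 0L, contig, blocks, read_len, strand)
}

sam_pair <- function(qname, contig, strand, lb, rb, read_len) {
  tlen <- as.integer(rb[nrow(rb), 2L] - lb[1L, 1L])
  dplyr::bind_rows(
    sam_fields(qname, 99L, contig, lb, read_len, strand,
               rnext = "=", pnext = as.integer(rb[1L, 1L]) + 1L,
               tlen = tlen),
    sam_fields(qname, 147L, contig, rb, read_len, strand,
               rnext = "=", pnext = as.integer(lb[1L, 1L]) + 1L,
               tlen = -tlen))
}

# flatten gene models into the tidy transcript layout
models_to_transcripts <- function(models) {
  out <- list()
  for (g in seq_len(nrow(models))) {
    iso <- models$isoforms[[g]]
    for (i in seq_len(nrow(iso))) {
      ex <- iso$exons[[i]]
      out[[length(out) + 1L]] <- tibble::tibble(
        transcript_id = iso$transcript_id[i],
        gene_id = models$gene_id[g],
        contig = models$contig[g], strand = models$strand[g],
        exons = list(ex), introns = list(blocks_to_introns(ex)),
        n_exons = nrow(ex))
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate a complete test data set
#'
#' Convenience wrapper: builds gene models and writes matched SAM
#' alignments and truth GTF.
#'
#' @param out_prefix Output path prefix; writes `<prefix>.sam` and
#'   `<prefix>.gtf`.
#' @param n_genes,seed,depth,read_len,paired,frag_mean,frag_sd See
#'   [make_gene_models()] and [simulate_alignments()].
#' @param ... Passed to [make_gene_models()].
#' @return A list with `sam`, `gtf`, `models`, `truth`.
#' @export
simulate_rnaseq <- function(out_prefix, n_genes = 20, seed = 1, depth = 50,
                            read_len = 75, paired = TRUE, frag_mean = 250,
                            frag_sd = 25, ...) {
  models <- make_gene_models(n_genes = n_genes, seed = seed, ...)
  sam <- paste0(out_prefix, ".sam")
  gtf <- paste0(out_prefix, ".gtf")
  res <- simulate_alignments(models, sam, gtf, depth = depth,
                             read_len = read_len, paired = paired,
                             frag_mean = frag_mean, frag_sd = frag_sd,
                             seed = seed)
  list(sam = sam, gtf = gtf, models = models, truth = res$truth)
}
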
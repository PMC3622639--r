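#' Read spliced alignments from a SAM file
#'
#' Parses a headered SAM file into the three tables the assembler works from:
#' one row per primary aligned read (with its genomic blocks as a list-column),
#' a splice-junction table aggregated across reads, and a mate-pair table.
#' Only primary, mapped alignments with mapping quality at or above `min_mapq`
#' are kept; everything else is counted in `skipped`.
#'
#' Coordinates are 0-based half-open throughout. A junction is stored as
#' `(donor, acceptor)` where `donor` is the first intronic base and `acceptor`
#' one past the last intronic base, so `donor < acceptor` on both strands;
#' on the minus strand the biological 5'/3' roles are mirrored. Junction
#' strand is taken from the `XS` tag when the aligner wrote one, else `"*"`.
#'
#' @param sam Path to a SAM file with a header.
#' @param min_mapq Minimum mapping quality; records below are skipped.
#'   Records with missing quality (255) are kept.
#' @return A list of class `alignment_set` with elements `reads`, `junctions`,
#'   `pairs` (tibbles), and `skipped` (count of records not stored).
#' @export
read_alignments <- function(sam, min_mapq = 0) {
  if (!file.exists(sam)) stop("alignment file not found: ", sam)
  first <- readLines(sam, n = 1L)
  if (length(first) == 0L || !startsWith(first, "@")) {
    stop("SAM file has no header: ", sam)
  }
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  total <- Rsamtools::countBam(bam)$records
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    tag = "XS",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  mc <- S4Vectors::mcols(ga)
  keep <- is.na(mc$mapq) | mc$mapq >= min_mapq
  ga <- ga[keep]
  mc <- S4Vectors::mcols(ga)
  skipped <- total - length(ga)

  rl <- IRanges::ranges(GenomicAlignments::grglist(ga))
  starts <- as.list(IRanges::start(rl))
  ends <- as.list(IRanges::end(rl))
  blocks <- purrr::map2(starts, ends, function(s, e) {
    cbind(as.integer(s) - 1L, as.integer(e))  # to 0-based half-open
  })
  xs <- mc$XS
  if (is.null(xs)) xs <- rep(NA_character_, length(ga))
  reads <- tibble::tibble(
    read_id = mc$qname,
    contig = as.character(GenomicAlignments::seqnames(ga)),
    strand = dplyr::if_else(is.na(xs), "*", as.character(xs)),
    mapq = mc$mapq,
    is_paired = bitwAnd(mc$flag, 1L) > 0L,
    is_first = bitwAnd(mc$flag, 64L) > 0L,
    blocks = blocks,
    njunc = purrr::map_int(blocks, ~ nrow(.x) - 1L)
  )

  junctions <- build_junction_table(reads)
  pairs <- build_pair_table(reads)
  structure(list(reads = reads, junctions = junctions, pairs = pairs,
                 skipped = skipped, n_records = total),
            class = "alignment_set")
}

# aggregate per-read junctions into a support table
build_junction_table <- function(reads) {
  spliced <- reads[reads$njunc > 0L, ]
  if (nrow(spliced) == 0L) {
    return(tibble::tibble(contig = character(), donor = integer(),
                          acceptor = integer(), strand = character(),
                          support = integer(), max_anchor = integer()))
  }
  per_read <- purrr::pmap(
    list(spliced$contig, spliced$strand, spliced$blocks),
    function(contig, strand, b) {
      intr <- blocks_to_introns(b)
      w <- b[, 2L] - b[, 1L]
      k <- nrow(intr)
      tibble::tibble(contig = contig, strand = strand,
                     donor = intr[, 1L], acceptor = intr[, 2L],
                     anchor = pmin(w[seq_len(k)], w[seq_len(k) + 1L]))
    })
  dplyr::bind_rows(per_read) |>
    dplyr::group_by(.data$contig, .data$donor, .data$acceptor) |>
    dplyr::summarise(
      strand = consensus_strand(.data$strand),
      support = dplyr::n(),
      max_anchor = max(.data$anchor),
      .groups = "drop") |>
    dplyr::arrange(.data$contig, .data$donor, .data$acceptor) |>
    dplyr::select("contig", "donor", "acceptor", "strand",
                  "support", "max_anchor")
}

consensus_strand <- function(s) {
  u <- unique(s[s != "*"])
  if (length(u) == 1L) u else "*"
}

# link mates by query name; keeps pairs with both primary mates on one contig
build_pair_table <- function(reads) {
  pr <- reads[reads$is_paired, ]
  empty <- tibble::tibble(read_id = character(), contig = character(),
                          strand = character(),
                          left_blocks = list(), right_blocks = list(),
                          left_njunc = integer(), right_njunc = integer(),
                          left_start = integer(), right_end = integer())
  if (nrow(pr) == 0L) return(empty)
  pr$start0 <- purrr::map_int(pr$blocks, ~ .x[1L, 1L])
  pr$end0 <- purrr::map_int(pr$blocks, ~ .x[nrow(.x), 2L])
  grp <- split(seq_len(nrow(pr)), pr$read_id)
  rows <- purrr::map(grp, function(idx) {
    if (length(idx) != 2L) return(NULL)
    a <- pr[idx[1L], ]; b <- pr[idx[2L], ]
    if (a$contig != b$contig) return(NULL)
    if (b$start0 < a$start0) { tmp <- a; a <- b; b <- tmp }
    tibble::tibble(
      read_id = a$read_id, contig = a$contig,
      strand = consensus_strand(c(a$strand, b$strand)),
      left_blocks = a$blocks, right_blocks = b$blocks,
      left_njunc = a$njunc, right_njunc = b$njunc,
      left_start = a$start0, right_end = b$end0)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty else dplyr::arrange(out, .data$contig,
                                                 .data$left_start)
}

#' Detect read-covered regions
#'
#' A region is a maximal genomic stretch in which every base is covered by at
#' least one read block, after bridging zero-coverage gaps of at most
#' `max_gap` bases. Introns between exons carry no body coverage, so the
#' exons of a gene typically come out as separate regions connected only
#' through the junction table.
#'
#' @param x An `alignment_set` or a reads tibble as produced by
#'   [read_alignments()].
#' @param max_gap Zero-coverage gaps of at most this many bases are bridged.
#' @param min_region_len Regions shorter than this are dropped as noise.
#' @return A tibble with one row per region: `region_id`, `contig`, `start`,
#'   `end` (0-based half-open) and `strand_hint` (`"+"`, `"-"`, `"both"` or
#'   `"."` from junctions touching the region).
#' @export
detect_regions <- function(x, max_gap = 0, min_region_len = 25) {
  reads <- if (inherits(x, "alignment_set")) x$reads else x
  junctions <- if (inherits(x, "alignment_set")) x$junctions else NULL
  if (nrow(reads) == 0L) {
    return(tibble::tibble(region_id = integer(), contig = character(),
                          start = integer(), end = integer(),
                          strand_hint = character()))
  }
  per_contig <- split(reads$blocks, reads$contig)
  out <- purrr::imap(per_contig, function(blks, contig) {
    m <- do.call(rbind, blks)
    ir <- IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L])
    cov <- IRanges::coverage(ir)
    sl <- IRanges::slice(cov, lower = 1L, rangesOnly = TRUE)
    merged <- IRanges::reduce(sl, min.gapwidth = max_gap + 1L)
    merged <- merged[IRanges::width(merged) >= min_region_len]
    tibble::tibble(contig = contig,
                   start = IRanges::start(merged) - 1L,
                   end = IRanges::end(merged))
  })
  regions <- dplyr::bind_rows(out) |>
    dplyr::arrange(.data$contig, .data$start) |>
    dplyr::mutate(region_id = dplyr::row_number(), .before = 1L)
  regions$strand_hint <- region_strand_hint(regions, junctions)
  regions
}

region_strand_hint <- function(regions, junctions) {
  if (is.null(junctions) || nrow(junctions) == 0L) {
    return(rep(".", nrow(regions)))
  }
  purrr::pmap_chr(regions[, c("contig", "start", "end")],
                  function(contig, start, end) {
    j <- junctions[junctions$contig == contig &
                     ((junctions$donor >= start & junctions$donor <= end) |
                      (junctions$acceptor >= start &
                         junctions$acceptor <= end)), ]
    u <- unique(j$strand[j$strand != "*"])
    if (length(u) == 0L) "." else if (length(u) == 1L) u else "both"
  })
}

#' Extract splice-site boundaries inside a region
#'
#' Returns the junction boundaries that fall strictly inside a region and
#' therefore split it into intervals. A junction whose donor lies in one
#' region and acceptor in another contributes one boundary to each.
#'
#' @param junctions Junction tibble from [read_alignments()].
#' @param region One-row region tibble from [detect_regions()].
#' @param min_support Minimum read support for a junction to count.
#' @param min_anchor Minimum maximal flanking-block length (nt).
#' @return A tibble with columns `pos`, `kind` (`"donor"` if the boundary is
#'   the genomic-left end of an intron, `"acceptor"` if the genomic-right
#'   end) and `strand`, sorted by position.
#' @export
extract_splice_sites <- function(junctions, region, min_support = 1,
                                 min_anchor = 8) {
  j <- junctions[junctions$contig == region$contig &
                   junctions$support >= min_support &
                   junctions$max_anchor >= min_anchor, ]
  don <- j[j$donor > region$start & j$donor < region$end, ]
  acc <- j[j$acceptor > region$start & j$acceptor < region$end, ]
  out <- dplyr::bind_rows(
    tibble::tibble(pos = don$donor, kind = "donor", strand = don$strand),
    tibble::tibble(pos = acc$acceptor, kind = "acceptor",
                   strand = acc$strand))
  dplyr::distinct(out) |> dplyr::arrange(.data$pos, .data$kind)
}

#' Estimate fragment length statistics from proper pairs
#'
#' Uses pairs whose mates are both unspliced and, when `regions` is given,
#' co-located in a single covered region, so the genomic end-to-end span
#' equals the fragment length. A symmetric 5% trim (2.5% per tail) guards
#' against chimeric pairs; the trimmed standard deviation is rescaled by the
#' truncated-normal consistency factor so both estimates are unbiased for
#' Gaussian fragment lengths.
#'
#' @param pairs Pair tibble from [read_alignments()] (or an `alignment_set`).
#' @param regions Optional region tibble; restricts to intra-region pairs.
#' @param override Optional `c(f_l, f_sigma)`; returned verbatim, e.g. for
#'   single-end libraries.
#' @param trim Total two-sided trim fraction.
#' @return A one-row tibble of class `fragment_stats`: `f_l`, `f_sigma`,
#'   `n_used`.
#' @export
estimate_fragment_stats <- function(pairs, regions = NULL, override = NULL,
                                    trim = 0.05) {
  if (!is.null(override)) {
    stopifnot(length(override) == 2L, override[1] > 0, override[2] >= 0)
    return(new_fragment_stats(override[1], override[2], 0L))
  }
  if (inherits(pairs, "alignment_set")) pairs <- pairs$pairs
  el <- pairs[pairs$left_njunc == 0L & pairs$right_njunc == 0L, ]
  if (!is.null(regions) && nrow(el) > 0L) {
    ok <- purrr::pmap_lgl(
      el[, c("contig", "left_start", "right_end")],
      function(contig, left_start, right_end) {
        r <- regions[regions$contig == contig &
                       regions$start <= left_start &
                       regions$end >= right_end, ]
        nrow(r) > 0L
      })
    el <- el[ok, ]
  }
  if (nrow(el) == 0L) {
    stop("no pairs eligible for fragment-length estimation; ",
         "pass fragment parameters via `override = c(f_l, f_sigma)`")
  }
  frag <- el$right_end - el$left_start
  q <- stats::quantile(frag, c(trim / 2, 1 - trim / 2), names = FALSE,
                       type = 7)
  kept <- frag[frag >= q[1] & frag <= q[2]]
  z <- stats::qnorm(1 - trim / 2)
  v <- 1 - 2 * z * stats::dnorm(z) / (1 - trim)  # var. of central normal slice
  new_fragment_stats(mean(kept), stats::sd(kept) / sqrt(v), length(kept))
}

new_fragment_stats <- function(f_l, f_sigma, n_used) {
  out <- tibble::tibble(f_l = as.numeric(f_l), f_sigma = as.numeric(f_sigma),
                        n_used = as.integer(n_used))
  class(out) <- c("fragment_stats", class(out))
  out
}

# admissible fragment-length window f_l +/- 2 f_sigma
frag_window <- function(stats) {
  c(stats$f_l - 2 * stats$f_sigma, stats$f_l + 2 * stats$f_sigma)
}
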
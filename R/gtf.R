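#' Read transcript models from a GTF file
#'
#' Imports exon features grouped by `transcript_id` into the tidy transcript
#' representation used throughout the package (0-based half-open exon
#' coordinates, derived intron chains).
#'
#' @param path Path to a GTF file (1-based inclusive coordinates, exon
#'   features with `gene_id`/`transcript_id` attributes).
#' @return A tibble: `transcript_id`, `gene_id`, `contig`, `strand`,
#'   `exons` (list of two-column matrices), `introns` (list), `n_exons`.
#' @export
read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) {
    return(tibble::tibble(transcript_id = character(),
                          gene_id = character(), contig = character(),
                          strand = character(), exons = list(),
                          introns = list(), n_exons = integer()))
  }
  tb <- tibble::tibble(
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id %||%
                             S4Vectors::mcols(gr)$transcript_id),
    contig = as.character(GenomicAlignments::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr))
  tb |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      gene_id = dplyr::first(.data$gene_id),
      contig = dplyr::first(.data$contig),
      strand = dplyr::first(.data$strand),
      exons = list(cbind(.data$start, .data$end)),
      .groups = "drop") |>
    dplyr::mutate(
      introns = purrr::map(.data$exons, blocks_to_introns),
      n_exons = purrr::map_int(.data$exons, nrow)) |>
    dplyr::arrange(.data$contig,
                   purrr::map_dbl(.data$exons, ~ .x[1L, 1L]),
                   .data$transcript_id)
}

#' Write transcript models to a GTF file
#'
#' Emits one `transcript` line and one `exon` line per exon, 1-based
#' inclusive, with `gene_id` then `transcript_id` attributes. Output
#' ordering and formatting are fully deterministic.
#'
#' @param transcripts Tibble with `gene_id`, `transcript_id`, `contig`,
#'   `strand` and an `exons` list-column of two-column matrices (0-based
#'   half-open).
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path, source = "isocover") {
  if (inherits(transcripts, "isocover_fit")) {
    transcripts <- transcripts$transcripts
  }
  tx <- transcripts |>
    dplyr::mutate(t_start = purrr::map_dbl(.data$exons, ~ .x[1L, 1L])) |>
    dplyr::arrange(.data$contig, .data$t_start, .data$transcript_id)
  lines <- character(0)
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    strand <- tx$strand[i]
    if (!strand %in% c("+", "-")) strand <- "."
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id[i], tx$transcript_id[i])
    lines <- c(lines,
               paste(tx$contig[i], source, "transcript",
                     ex[1L, 1L] + 1L, ex[nrow(ex), 2L], ".", strand, ".",
                     attrs, sep = "\t"),
               paste(tx$contig[i], source, "exon",
                     ex[, 1L] + 1L, ex[, 2L], ".", strand, ".",
                     attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
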
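#' Exon-level match decision
#'
#' Implements the three exon match criteria: an internal predicted exon must
#' match an internal annotated exon at both ends; a terminal predicted exon
#' must match an annotated exon at its splice-site end and be included in
#' it; an exon not bounded by splice sites must be included in an annotated
#' exon. All boundary comparisons allow a margin of `v` bases.
#'
#' @param pred,ref Numeric length-2 vectors `c(start, end)` (0-based
#'   half-open).
#' @param kind `"internal"`, `"terminal"` or `"unbounded"` (the predicted
#'   exon's context in its transcript).
#' @param v Boundary margin in nt.
#' @param splice_side For terminal exons, which end is the splice site:
#'   `"left"` (last exon of a transcript) or `"right"` (first exon).
#' @return Logical.
#' @export
exon_match <- function(pred, ref, kind = c("internal", "terminal",
                                           "unbounded"),
                       v = 0, splice_side = NULL) {
  kind <- match.arg(kind)
  within <- function(a, b) abs(a - b) <= v
  contained <- pred[1] >= ref[1] - v && pred[2] <= ref[2] + v
  switch(kind,
    internal = within(pred[1], ref[1]) && within(pred[2], ref[2]),
    terminal = {
      stopifnot(splice_side %in% c("left", "right"))
      sp_ok <- if (splice_side == "left") within(pred[1], ref[1])
               else within(pred[2], ref[2])
      sp_ok && contained
    },
    unbounded = contained)
}

# does chain p (k x 2) occur as a consecutive subchain of chain r (m x 2),
# every boundary within +/- v?
is_consecutive_subchain <- function(p, r, v = 0) {
  k <- nrow(p); m <- nrow(r)
  if (k == 0L) return(TRUE)
  if (k > m) return(FALSE)
  for (off in 0:(m - k)) {
    seg <- r[(off + 1L):(off + k), , drop = FALSE]
    if (all(abs(seg - p) <= v)) return(TRUE)
  }
  FALSE
}

# offsets at which p matches inside r (for effective coverage)
subchain_offsets <- function(p, r, v = 0) {
  k <- nrow(p); m <- nrow(r)
  if (k == 0L || k > m) return(integer(0))
  hits <- integer(0)
  for (off in 0:(m - k)) {
    seg <- r[(off + 1L):(off + k), , drop = FALSE]
    if (all(abs(seg - p) <= v)) hits <- c(hits, off)
  }
  hits
}

#' Transcript-level match decision
#'
#' In `strict` mode a prediction matches a reference when all of the
#' prediction's introns appear consecutively in the reference's intron
#' chain (each boundary within `v`). In `compatible` mode the relation is
#' symmetric: either intron chain may be the consecutive subchain of the
#' other. Single-exon transcripts match single-exon transcripts by
#' containment with `v` slack; single- and multi-exon transcripts never
#' match each other.
#'
#' @param pred,ref One-row transcript tibbles (with `exons`, `introns`,
#'   `contig`, `strand`).
#' @param v Boundary margin in nt.
#' @param mode `"strict"` or `"compatible"`.
#' @return Logical.
#' @export
transcript_match <- function(pred, ref, v = 0,
                             mode = c("strict", "compatible")) {
  mode <- match.arg(mode)
  if (pred$contig != ref$contig) return(FALSE)
  if (!strand_compatible(pred$strand, ref$strand)) return(FALSE)
  pi <- pred$introns[[1L]]; ri <- ref$introns[[1L]]
  if (nrow(pi) == 0L && nrow(ri) == 0L) {
    pe <- pred$exons[[1L]]; re <- ref$exons[[1L]]
    return(pe[1L, 1L] >= re[1L, 1L] - v && pe[1L, 2L] <= re[1L, 2L] + v)
  }
  if (nrow(pi) == 0L || nrow(ri) == 0L) return(FALSE)
  if (is_consecutive_subchain(pi, ri, v)) return(TRUE)
  mode == "compatible" && is_consecutive_subchain(ri, pi, v)
}

#' Effective coverage of a matched transcript pair
#'
#' The fraction of the assessed transcript's exons lying in the longest
#' matched consecutive stretch. A matched subchain of `m` introns spans
#' `m + 1` exons of the containing transcript.
#'
#' @param pred,ref One-row transcript tibbles; [transcript_match()] must
#'   hold for the pair.
#' @param v Boundary margin.
#' @param of Which side to assess: `"ref"` (default) or `"pred"`.
#' @param mode Match mode, as in [transcript_match()].
#' @return Fraction in `[0, 1]` (0 if the pair does not match).
#' @export
effective_coverage <- function(pred, ref, v = 0, of = c("ref", "pred"),
                               mode = c("strict", "compatible")) {
  of <- match.arg(of)
  mode <- match.arg(mode)
  pi <- pred$introns[[1L]]; ri <- ref$introns[[1L]]
  n_ref <- nrow(ri) + 1L
  n_pred <- nrow(pi) + 1L
  if (nrow(pi) == 0L && nrow(ri) == 0L) {
    return(as.numeric(transcript_match(pred, ref, v, mode)))
  }
  matched <- 0L
  if (nrow(pi) > 0L && nrow(ri) > 0L) {
    if (length(subchain_offsets(pi, ri, v))) matched <- nrow(pi) + 1L
    else if (mode == "compatible" && length(subchain_offsets(ri, pi, v))) {
      matched <- nrow(ri) + 1L
    }
  }
  if (matched == 0L) return(0)
  matched / if (of == "ref") n_ref else n_pred
}

#' Recall, precision and F-value from match counts
#'
#' `recall = K / M` and `precision = K' / N` when `K` of `M` reference
#' transcripts match `K'` of `N` predictions;
#' `F = 2 * recall * precision / (recall + precision)`. Values are reported
#' to three decimals, rounding half up, matching the convention of
#' published accuracy tables.
#'
#' @param matched_ref,n_ref Matched and total reference transcripts.
#' @param matched_pred,n_pred Matched and total predicted transcripts.
#' @return One-row tibble: `k`, `m`, `k_prime`, `n`, `recall`, `precision`,
#'   `f_value`.
#' @export
accuracy_from_counts <- function(matched_ref, n_ref, matched_pred, n_pred) {
  recall <- if (n_ref > 0) round_half_up(matched_ref / n_ref) else 0
  precision <- if (n_pred > 0) round_half_up(matched_pred / n_pred) else 0
  tibble::tibble(k = matched_ref, m = n_ref, k_prime = matched_pred,
                 n = n_pred, recall = recall, precision = precision,
                 f_value = f_value(recall, precision))
}

#' F-value from recall and precision
#'
#' Harmonic mean `2RP / (R + P)`, 0 when both are 0, reported to three
#' decimals rounding half up.
#'
#' @param recall,precision Accuracy components.
#' @return Numeric.
#' @export
f_value <- function(recall, precision) {
  if (recall + precision <= 0) return(0)
  round_half_up(2 * recall * precision / (recall + precision))
}

#' Evaluate predicted transcripts against a reference annotation
#'
#' Computes transcript-level accuracy by intron-chain matching (strict or
#' compatible, with boundary margin `v`), exon-level accuracy under the
#' three exon match criteria, and recall/precision at every effective
#' coverage cutoff in `0.1, 0.2, ..., 1.0`. A reference transcript counts
#' as matched when at least one prediction matches it with effective
#' coverage at or above the cutoff, and vice versa.
#'
#' @param pred,ref GTF paths or transcript tibbles
#'   ([read_gtf_transcripts()] layout).
#' @param v Boundary margin in nt (`V = 10` is customary for curated
#'   references with uncertain ends; 0 for exact simulated truth).
#' @param multi_exon_only Drop single-exon transcripts from both sets
#'   before counting (single-exon assemblies are predominantly artifacts).
#' @param coverage_cutoff Effective-coverage cutoff for the headline
#'   numbers.
#' @param mode `"strict"` or `"compatible"` intron-chain matching.
#' @return An object of class `accuracy_report`; see [glance.accuracy_report()]
#'   and [tidy.accuracy_report()].
#' @export
accuracy_report <- function(pred, ref, v = 0, multi_exon_only = FALSE,
                            coverage_cutoff = 0,
                            mode = c("strict", "compatible")) {
  mode <- match.arg(mode)
  if (is.character(pred)) pred <- read_gtf_transcripts(pred)
  if (is.character(ref)) ref <- read_gtf_transcripts(ref)
  if (multi_exon_only) {
    pred <- pred[pred$n_exons > 1L, ]
    ref <- ref[ref$n_exons > 1L, ]
  }
  if (nrow(pred) == 0L) {
    warning("empty prediction set; precision reported as 0")
  }

  # all matching pred/ref pairs with effective coverage on both sides
  matches <- transcript_match_table(pred, ref, v, mode)

  cutoffs <- seq(0.1, 1, by = 0.1)
  curve <- purrr::map_dfr(cutoffs, function(ct) {
    counts_at_cutoff(matches, nrow(ref), nrow(pred), ct)
  })
  headline <- counts_at_cutoff(matches, nrow(ref), nrow(pred),
                               coverage_cutoff)
  exon <- exon_accuracy(pred, ref, v)

  structure(list(transcript = headline, exon = exon, curve = curve,
                 matches = matches,
                 spec = list(v = v, multi_exon_only = multi_exon_only,
                             coverage_cutoff = coverage_cutoff,
                             mode = mode)),
            class = "accuracy_report")
}

transcript_match_table <- function(pred, ref, v, mode) {
  out <- list()
  for (ri in seq_len(nrow(ref))) {
    rr <- ref[ri, ]
    for (pi in seq_len(nrow(pred))) {
      pp <- pred[pi, ]
      if (pp$contig != rr$contig) next
      if (!strand_compatible(pp$strand, rr$strand)) next
      if (!transcript_match(pp, rr, v, mode)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        ref_i = ri, pred_i = pi,
        ec_ref = effective_coverage(pp, rr, v, "ref", mode),
        ec_pred = effective_coverage(pp, rr, v, "pred", mode))
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(ref_i = integer(), pred_i = integer(),
                   ec_ref = numeric(), ec_pred = numeric())
}

counts_at_cutoff <- function(matches, n_ref, n_pred, cutoff) {
  k <- length(unique(matches$ref_i[matches$ec_ref >= cutoff]))
  kp <- length(unique(matches$pred_i[matches$ec_pred >= cutoff]))
  dplyr::mutate(accuracy_from_counts(k, n_ref, kp, n_pred),
                cutoff = cutoff, .before = 1L)
}

# classify each distinct exon of a transcript set
exon_inventory <- function(tx) {
  if (nrow(tx) == 0L) {
    return(tibble::tibble(contig = character(), strand = character(),
                          start = integer(), end = integer(),
                          kind = character(), splice_side = character()))
  }
  out <- list()
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    n <- nrow(ex)
    kind <- if (n == 1L) "unbounded" else
      c("terminal", rep("internal", max(0L, n - 2L)), "terminal")
    side <- if (n == 1L) NA_character_ else
      c("right", rep(NA_character_, max(0L, n - 2L)), "left")
    out[[i]] <- tibble::tibble(contig = tx$contig[i], strand = tx$strand[i],
                               start = ex[, 1L], end = ex[, 2L],
                               kind = kind, splice_side = side)
  }
  dplyr::bind_rows(out) |> dplyr::distinct()
}

exon_accuracy <- function(pred, ref, v) {
  pe <- exon_inventory(pred)
  re <- exon_inventory(ref)
  re_distinct <- dplyr::distinct(re[, c("contig", "strand", "start",
                                        "end")])
  re_internal <- dplyr::distinct(
    re[re$kind == "internal", c("contig", "strand", "start", "end")])
  pred_hit <- logical(nrow(pe))
  ref_hit_keys <- character(0)
  for (i in seq_len(nrow(pe))) {
    cand <- if (pe$kind[i] == "internal") re_internal else re_distinct
    cand <- cand[cand$contig == pe$contig[i] &
                   strand_compatible(cand$strand, pe$strand[i]) &
                   cand$start < pe$end[i] + v + 1 &
                   cand$end > pe$start[i] - v - 1, ]
    for (r in seq_len(nrow(cand))) {
      if (exon_match(c(pe$start[i], pe$end[i]),
                     c(cand$start[r], cand$end[r]),
                     pe$kind[i], v, pe$splice_side[i])) {
        pred_hit[i] <- TRUE
        ref_hit_keys <- c(ref_hit_keys,
                          paste(cand$contig[r], cand$strand[r],
                                cand$start[r], cand$end[r]))
      }
    }
  }
  pe_distinct <- dplyr::distinct(pe[, c("contig", "strand", "start",
                                        "end")])
  pe_key <- paste(pe$contig, pe$strand, pe$start, pe$end)
  hit_key <- unique(pe_key[pred_hit])
  matched_pred <- sum(paste(pe_distinct$contig, pe_distinct$strand,
                            pe_distinct$start, pe_distinct$end) %in%
                        hit_key)
  accuracy_from_counts(length(unique(ref_hit_keys)), nrow(re_distinct),
                       matched_pred, nrow(pe_distinct))
}

#' @describeIn accuracy_report One-row summary (transcript- and exon-level
#'   counts, recall, precision, F-value).
#' @param x An `accuracy_report`.
#' @param ... Unused.
#' @export
glance.accuracy_report <- function(x, ...) {
  dplyr::bind_cols(
    dplyr::rename_with(x$transcript, ~ paste0("tx_", .x)),
    dplyr::rename_with(x$exon, ~ paste0("exon_", .x)))
}

#' @describeIn accuracy_report The recall/precision curve over
#'   effective-coverage cutoffs, one row per cutoff.
#' @export
tidy.accuracy_report <- function(x, ...) {
  x$curve
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Transcript assembly accuracy (", x$spec$mode, " mode, V = ",
      x$spec$v, if (x$spec$multi_exon_only) ", multi-exon only", ")\n",
      sep = "")
  cat(sprintf("  transcripts: K = %d / M = %d, K' = %d / N = %d\n",
              x$transcript$k, x$transcript$m, x$transcript$k_prime,
              x$transcript$n))
  cat(sprintf("  recall = %.3f  precision = %.3f  F = %.3f\n",
              x$transcript$recall, x$transcript$precision,
              x$transcript$f_value))
  cat(sprintf("  exons: recall = %.3f  precision = %.3f\n",
              x$exon$recall, x$exon$precision))
  invisible(x)
}

#' Plot precision/recall against the effective-coverage cutoff
#'
#' @param object An `accuracy_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve, c("recall", "precision"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "effective coverage cutoff", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
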
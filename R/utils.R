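# internal helpers shared across modules

# round half away from zero to `digits` decimals (table-style rounding;
# base round() is banker's rounding)
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# canonical string key for an intron (donor, acceptor are 0-based genomic,
# donor = first intronic base, acceptor = one past the last intronic base)
intron_key <- function(contig, donor, acceptor, strand = "*") {
  paste0(contig, ":", donor, "-", acceptor, ":", strand)
}

# a chain of introns as a single key; m is a k x 2 matrix (donor, acceptor)
chain_key <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return("")
  paste(paste0(m[, 1], "-", m[, 2]), collapse = "|")
}

# empty 0 x 2 integer matrix used for "no blocks"/"no introns"
empty_mat2 <- function() matrix(integer(0), ncol = 2L)

# introns implied by an ordered block matrix (gaps between consecutive blocks)
blocks_to_introns <- function(blocks) {
  k <- nrow(blocks)
  if (k < 2L) return(empty_mat2())
  cbind(blocks[-k, 2L], blocks[-1L, 1L])
}

# strand compatibility: "." / "*" match anything
strand_compatible <- function(a, b) {
  a %in% c(".", "*") | b %in% c(".", "*") | a == b
}

# deterministic lexicographic comparison of two numeric vectors:
# -1 if a < b, 0 if equal, 1 if a > b (shorter vector wins ties on prefix)
lex_cmp <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    d <- a[seq_len(n)] - b[seq_len(n)]
    i <- which(d != 0)
    if (length(i)) return(sign(d[i[1L]]))
  }
  sign(length(a) - length(b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# sample() without the scalar-x surprise (sample(2:2, 1) samples from 1:2)
resample <- function(x, ...) x[sample.int(length(x), ...)]
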
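# Shared low-level encodings and numeric helpers.

# Base coding: A=1 C=2 G=3 T=4, gap=5, unknown=6.  Anything else maps to NA.
.BASES <- c("A", "C", "G", "T")
.ALPHABET <- c("A", "C", "G", "T", "-", "N")
.GAP_CODE <- 5L
.UNKNOWN_CODE <- 6L

.make_code_lut <- function() {
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt(paste(.ALPHABET, collapse = ""))] <- seq_along(.ALPHABET)
  lut
}
.CODE_LUT <- .make_code_lut()

# Encode one sequence string to integer codes (NA for illegal characters).
.encode <- function(x) {
  ints <- utf8ToInt(x)
  out <- rep(NA_integer_, length(ints))
  ok <- ints >= 1L & ints <= 127L
  out[ok] <- .CODE_LUT[ints[ok]]
  out
}

.decode <- function(codes) {
  intToUtf8(utf8ToInt(paste(.ALPHABET, collapse = ""))[codes])
}

# The 10 unordered diploid genotypes over A,C,G,T, in lexicographic order.
.GT_PAIRS <- local({
  m <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  m <- m[order(m[, "row"], m[, "col"]), , drop = FALSE]
  cbind(x = m[, "row"], y = m[, "col"])
})
.GT_NAMES <- apply(.GT_PAIRS, 1L, function(p) paste(.BASES[p], collapse = "/"))

# 4x4 lookup: unordered pair of base codes -> genotype index 1..10.
.PIDX <- local({
  m <- matrix(NA_integer_, 4L, 4L)
  for (g in seq_len(nrow(.GT_PAIRS))) {
    m[.GT_PAIRS[g, 1L], .GT_PAIRS[g, 2L]] <- g
    m[.GT_PAIRS[g, 2L], .GT_PAIRS[g, 1L]] <- g
  }
  m
})

# log P(observed base b | genotype {x,y}, error prob e) for all b and all 10
# genotypes, as a 4 x 10 matrix.  P(b | a) = 1-e if b == a else e/3; the two
# chromosomes are sampled with probability 1/2 each.
.genotype_obs_logprob <- function(e) {
  p_base <- matrix(e / 3, 4L, 4L)
  diag(p_base) <- 1 - e
  m <- matrix(NA_real_, 4L, 10L, dimnames = list(.BASES, .GT_NAMES))
  for (g in 1:10) {
    m[, g] <- log(0.5 * p_base[, .GT_PAIRS[g, 1L]] + 0.5 * p_base[, .GT_PAIRS[g, 2L]])
  }
  m
}

# Row-wise log-sum-exp with max subtraction (underflow guard).
.row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

.phred_to_error <- function(q) 10^(-q / 10)
.error_to_phred <- function(e, max_q = 40L) {
  q <- ifelse(e <= 0, max_q, round(-10 * log10(e)))
  as.integer(pmin(q, max_q))
}

.qual_to_int <- function(qual_string) utf8ToInt(qual_string) - 33L
.int_to_qual <- function(q) intToUtf8(q + 33L)

# Reverse complement over the A/C/G/T/N alphabet (all read sequences).
.revcomp <- function(x) {
  .revstring(chartr("ACGTN", "TGCAN", x))
}

.revstring <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}
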
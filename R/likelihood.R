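# Diploid genotype likelihoods per alignment column, and the
# genotype-concordance score P_genotype for a candidate allele pair.

#' Per-column diploid genotype log-likelihoods from a pileup
#'
#' For a single alignment column with observed bases `b` and Phred
#' qualities `Q` (error probability `e = 10^(-Q/10)`), each of the 10
#' unordered diploid genotypes `{x, y}` is scored as the sum over reads of
#' `log( 0.5 * P(b | x, e) + 0.5 * P(b | y, e) )`, where
#' `P(b | a, e) = 1 - e` when `b == a` and `e / 3` otherwise (independent
#' reads, symmetric sequencing error).  An empty pileup returns 0 for every
#' genotype (uninformative).
#'
#' @param bases Character vector of observed bases (`A`/`C`/`G`/`T`).
#' @param quals Integer vector of Phred qualities, same length.
#' @return Named numeric vector of 10 genotype log-likelihoods
#'   (`"A/A"`, `"A/C"`, ..., `"T/T"`).
#' @examples
#' site_likelihoods(rep("A", 10), rep(30L, 10))
#' @export
site_likelihoods <- function(bases, quals) {
  stopifnot(length(bases) == length(quals))
  ll <- stats::setNames(numeric(10L), .GT_NAMES)
  if (length(bases) == 0L) return(ll)
  codes <- match(bases, .BASES)
  stopifnot(!anyNA(codes), all(quals >= 0))
  for (q in unique(quals)) {
    m <- .genotype_obs_logprob(.phred_to_error(q))
    cnt <- tabulate(codes[quals == q], 4L)
    ll <- ll + as.vector(cnt %*% m)
  }
  ll
}

#' Genotype likelihoods across all columns of a locus
#'
#' Builds, for every exon of `locus`, the per-column genotype
#' log-likelihood matrix from the assigned reads and normalizes each column
#' across the 10 genotypes (log-sum-exp), so that columns act as genotype
#' posteriors under a uniform genotype prior.  Bases below `qual_floor` are
#' excluded.
#'
#' @param reads Assigned-read data.frame for one sample at one locus.
#' @param dict An `hla_dictionary`.
#' @param locus Locus identifier.
#' @param qual_floor Minimum Phred quality for a base to count (default 5).
#' @return Object of class `hla_genotype_likelihoods`: list with `locus` and
#'   per-exon entries holding `loglik` (L x 10), `norm` (column-normalized
#'   L x 10) and `counts` (L x 4 base counts).
#' @export
genotype_likelihoods <- function(reads, dict, locus, qual_floor = 5L) {
  lc <- .get_locus(dict, locus)
  out <- list(locus = locus, exons = list())
  for (exon in names(lc$exons)) {
    L <- lc$exons[[exon]]$length
    sel <- reads$locus == locus & reads$exon == exon
    obs <- .collect_observations(reads[sel, , drop = FALSE], qual_floor)
    ll <- matrix(0, L, 10L, dimnames = list(NULL, .GT_NAMES))
    counts <- matrix(0L, L, 4L, dimnames = list(NULL, .BASES))
    if (length(obs$col) > 0L) {
      for (q in unique(obs$qual)) {
        qsel <- obs$qual == q
        cnt <- matrix(
          tabulate((obs$base[qsel] - 1L) * L + obs$col[qsel], nbins = 4L * L),
          L, 4L
        )
        ll <- ll + cnt %*% .genotype_obs_logprob(.phred_to_error(q))
        counts <- counts + cnt
      }
    }
    norm <- ll - .row_logsumexp(ll)
    out$exons[[exon]] <- list(loglik = ll, norm = norm, counts = counts)
  }
  structure(out, class = "hla_genotype_likelihoods")
}

# Flatten reads into parallel vectors of (column, base code, quality),
# keeping only known bases at or above the quality floor.
.collect_observations <- function(reads, qual_floor) {
  if (nrow(reads) == 0L) {
    return(list(col = integer(0), base = integer(0), qual = integer(0)))
  }
  cols <- vector("list", nrow(reads))
  bases <- vector("list", nrow(reads))
  quals <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    b <- .encode(reads$seq[i])
    q <- .qual_to_int(reads$qual[i])
    ok <- !is.na(b) & b <= 4L & q >= qual_floor
    cols[[i]] <- reads$start[i] + which(ok) - 1L
    bases[[i]] <- b[ok]
    quals[[i]] <- q[ok]
  }
  list(col = unlist(cols), base = unlist(bases), qual = unlist(quals))
}

#' Genotype-concordance score for one allele pair
#'
#' Sums, over every sequenced alignment column, the column-normalized
#' log-likelihood of the base genotype implied by the two alleles.  Columns
#' where either allele carries a gap or unknown base are skipped.  Because
#' per-column values are normalized across the 10 genotypes, columns at
#' which all candidate pairs imply the same genotype shift every pair's
#' score equally and cancel under the caller's final normalization.
#'
#' @param allele1,allele2 4-digit allele names present in the dictionary.
#' @param likelihoods An `hla_genotype_likelihoods` for the same locus.
#' @param dict An `hla_dictionary`.
#' @return Log-probability (scalar); symmetric in the two alleles.
#' @export
p_genotype <- function(allele1, allele2, likelihoods, dict) {
  stopifnot(inherits(likelihoods, "hla_genotype_likelihoods"))
  locus <- likelihoods$locus
  lc <- .get_locus(dict, locus)
  for (a in c(allele1, allele2)) {
    if (!a %in% lc$alleles) stop("allele not in dictionary: ", a)
  }
  total <- 0
  for (exon in names(likelihoods$exons)) {
    e <- lc$exons[[exon]]
    b1 <- e$mat[allele1, ]
    b2 <- e$mat[allele2, ]
    valid <- b1 <= 4L & b2 <= 4L
    if (!any(valid)) next
    g <- .PIDX[cbind(b1[valid], b2[valid])]
    total <- total + sum(likelihoods$exons[[exon]]$norm[cbind(which(valid), g)])
  }
  total
}
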
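# Phase-consistency scoring: reads spanning adjacent polymorphic sites
# carry direct evidence of which variant bases co-occur on one chromosome.

#' Collect two-site haplotype evidence at adjacent polymorphic columns
#'
#' "Adjacent" means consecutive entries of the per-exon polymorphic-column
#' list; site pairs never straddle exons (no read spans an exon boundary).
#' For each pair, reads covering both columns with known bases of at least
#' `qual_floor` quality are tallied by their observed two-site haplotype.
#'
#' @param reads Assigned-read data.frame for one sample at one locus
#'   (filtered, alignment-space coordinates).
#' @param dict An `hla_dictionary`.
#' @param locus Locus identifier.
#' @param qual_floor Minimum Phred quality (default 5).
#' @return Object of class `hla_site_pairs`: list of records, each with
#'   `exon`, `col1`, `col2`, `counts` (length-16 tally indexed by
#'   `(base1-1)*4 + base2`) and `n` (total spanning reads); only pairs with
#'   at least one spanning read are listed.
#' @export
collect_site_pairs <- function(reads, dict, locus, qual_floor = 5L) {
  lc <- .get_locus(dict, locus)
  records <- list()
  for (exon in names(lc$exons)) {
    poly <- lc$exons[[exon]]$polymorphic
    if (length(poly) < 2L) next
    sel <- which(reads$locus == locus & reads$exon == exon)
    if (length(sel) == 0L) next
    starts <- reads$start[sel]
    ends <- starts + nchar(reads$seq[sel]) - 1L
    enc <- lapply(sel, function(i) .encode(reads$seq[i]))
    qint <- lapply(sel, function(i) .qual_to_int(reads$qual[i]))
    for (t in seq_len(length(poly) - 1L)) {
      c1 <- poly[t]; c2 <- poly[t + 1L]
      span <- which(starts <= c1 & ends >= c2)
      if (length(span) == 0L) next
      counts <- integer(16L)
      for (j in span) {
        o1 <- c1 - starts[j] + 1L
        o2 <- c2 - starts[j] + 1L
        b1 <- enc[[j]][o1]; b2 <- enc[[j]][o2]
        if (is.na(b1) || is.na(b2) || b1 > 4L || b2 > 4L) next
        if (qint[[j]][o1] < qual_floor || qint[[j]][o2] < qual_floor) next
        h <- (b1 - 1L) * 4L + b2
        counts[h] <- counts[h] + 1L
      }
      if (sum(counts) == 0L) next
      records[[length(records) + 1L]] <- list(
        exon = exon, col1 = c1, col2 = c2, counts = counts, n = sum(counts)
      )
    }
  }
  structure(records, class = "hla_site_pairs", locus = locus)
}

#' Binomial phase-consistency score for one allele pair
#'
#' At each adjacent polymorphic site pair, the candidate allele pair
#' predicts (at most) two two-site haplotypes.  With `k` spanning reads
#' matching either predicted haplotype out of `n` informative spanning
#' reads, the site pair contributes `log dbinom(k, n, 1 - p_err)`; reads
#' matching neither predicted haplotype count in `n` but not `k`.  When both
#' alleles are identical at both sites the single predicted haplotype is
#' scored with the same formula.  Site pairs where either allele carries a
#' gap or unknown base are skipped, and pairs with `n = 0` contribute 0.
#' Contributions sum over all site pairs, so the total log-probability is
#' always non-positive and is symmetric in the two alleles.
#'
#' @param allele1,allele2 4-digit allele names present in the dictionary.
#' @param evidence An `hla_site_pairs` object from [collect_site_pairs()].
#' @param dict An `hla_dictionary`.
#' @param p_err Assumed per-read phase error rate (default 0.01).
#' @return List with `log_p` (total log-probability) and `informative`
#'   (number of site pairs with `n > 0` that were scored).
#' @export
p_phase <- function(allele1, allele2, evidence, dict, p_err = 0.01) {
  stopifnot(inherits(evidence, "hla_site_pairs"), p_err > 0, p_err < 1)
  locus <- attr(evidence, "locus")
  lc <- .get_locus(dict, locus)
  for (a in c(allele1, allele2)) {
    if (!a %in% lc$alleles) stop("allele not in dictionary: ", a)
  }
  total <- 0
  informative <- 0L
  for (rec in unclass(evidence)) {
    e <- lc$exons[[rec$exon]]
    b <- c(e$mat[allele1, rec$col1], e$mat[allele1, rec$col2],
           e$mat[allele2, rec$col1], e$mat[allele2, rec$col2])
    if (any(b > 4L)) next  # haplotypes undefined for this candidate
    h1 <- (b[1L] - 1L) * 4L + b[2L]
    h2 <- (b[3L] - 1L) * 4L + b[4L]
    k <- rec$counts[h1] + if (h2 != h1) rec$counts[h2] else 0L
    total <- total + stats::dbinom(k, rec$n, 1 - p_err, log = TRUE)
    informative <- informative + 1L
  }
  list(log_p = total, informative = informative)
}
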
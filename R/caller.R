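# The genotype caller: enumerate every unordered pair of 4-digit alleles at
# a locus, combine genotype concordance, phase consistency and population
# frequency priors, normalize, and report the matching set plus a
# frequency-resolved best guess.

#' Population-frequency prior for an allele pair
#'
#' The prior probability of carrying alleles `i` and `j` is the product of
#' their population frequencies, `f_i * f_j`, exactly as stated (no
#' Hardy-Weinberg heterozygote factor of 2 by default; set `hwe = TRUE` to
#' add it).  Alleles missing from the table receive the floor frequency.
#' With `population = NULL` (ancestry unknown) the prior is uniform across
#' pairs, returned as 0 on the log scale since any constant cancels under
#' normalization.
#'
#' @param allele1,allele2 4-digit allele names.
#' @param freqs An `hla_frequencies` object (may be `NULL` when
#'   `population` is `NULL`).
#' @param population Population label, or `NULL` for a uniform prior.
#' @param floor Frequency floor for missing alleles (default 1e-5).
#' @param hwe Add `log(2)` for heterozygous pairs (default `FALSE`).
#' @return Log prior probability.
#' @export
p_frequency <- function(allele1, allele2, freqs = NULL, population = NULL,
                        floor = 1e-5, hwe = FALSE) {
  if (is.null(population)) return(0)
  f <- allele_frequency(freqs, population, c(allele1, allele2), floor = floor)
  log(f[1L]) + log(f[2L]) + if (hwe && allele1 != allele2) log(2) else 0
}

#' Call the HLA genotype at one locus for one sample
#'
#' Systematically evaluates all `n(n+1)/2` unordered pairs of dictionary
#' alleles: each pair is scored by the product (log-space sum) of its
#' genotype concordance ([p_genotype()]), its binomial phase consistency
#' ([p_phase()]) and its population-frequency prior ([p_frequency()]), and
#' the combined scores are normalized to posterior probabilities summing to
#' 1 over all pairs.  Two results are reported: the *matching set* -- every
#' pair attaining the maximal genotype-times-phase score (within relative
#' tolerance 1e-9), i.e. all pairs the sequence data alone cannot
#' distinguish -- and the *best guess*, the pair with maximal posterior
#' once frequency information is added (ties broken by allele-name order so
#' runs are reproducible).
#'
#' QC flags: `low_coverage` when mean exon depth is below `min_depth`;
#' `possible_contamination` when at least 2 columns (of depth >= 10) show 3
#' or more bases each supported by at least 10% of reads, the signature of a
#' sample mixture (four distinct chromosomes).
#'
#' @param reads Assigned-read data.frame for one sample (rows at other loci
#'   are ignored), normally after [misalignment_filter()].
#' @param dict An `hla_dictionary`.
#' @param locus Locus identifier.
#' @param freqs An `hla_frequencies`, or `NULL`.
#' @param population Population label, or `NULL` for a uniform prior.
#' @param p_err Assumed phase error rate (default 0.01).
#' @param qual_floor Minimum base quality (default 5).
#' @param floor Frequency floor (default 1e-5).
#' @param min_depth Mean depth below which `low_coverage` is flagged
#'   (default 20).
#' @param hwe Heterozygote factor in the prior (default `FALSE`).
#' @param sample Sample id recorded in the call (defaults to the reads'
#'   sample).
#' @return Object of class `hla_call`: list with `status` (`"ok"` or
#'   `"no_call"`), `sample`, `locus`, `best` (character(2)),
#'   `best_2digit`, `posterior`, `matching_set` (data.frame `allele1`,
#'   `allele2`), `flags`, `mean_depth`, `n_reads` and `scores`, the full
#'   per-pair table (`allele1`, `allele2`, `log_p_genotype`, `log_p_phase`,
#'   `log_p_frequency`, `log_p_combined`, `posterior`).
#' @export
call_locus <- function(reads, dict, locus, freqs = NULL, population = NULL,
                       p_err = 0.01, qual_floor = 5L, floor = 1e-5,
                       min_depth = 20, hwe = FALSE, sample = NULL) {
  lc <- .get_locus(dict, locus)
  reads <- reads[reads$locus == locus, , drop = FALSE]
  if (is.null(sample)) {
    sample <- if (nrow(reads) > 0L) reads$sample[1L] else "sample"
  }
  if (nrow(reads) == 0L) {
    return(structure(list(status = "no_call", sample = sample, locus = locus,
                          best = c(NA_character_, NA_character_),
                          best_2digit = c(NA_character_, NA_character_),
                          posterior = NA_real_,
                          matching_set = NULL, flags = "no_reads",
                          mean_depth = 0, n_reads = 0L, scores = NULL),
                     class = "hla_call"))
  }
  alleles <- lc$alleles
  n <- length(alleles)
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  pi <- pairs[, "row"]; pj <- pairs[, "col"]

  gl <- genotype_likelihoods(reads, dict, locus, qual_floor = qual_floor)
  ev <- collect_site_pairs(reads, dict, locus, qual_floor = qual_floor)

  pg <- .pg_all_pairs(gl, lc, pi, pj)
  pp <- .pp_all_pairs(ev, lc, pi, pj, p_err)
  pf <- if (is.null(population)) {
    numeric(length(pi))
  } else {
    f <- allele_frequency(freqs, population, alleles, floor = floor)
    log(f[pi]) + log(f[pj]) + if (hwe) ifelse(pi != pj, log(2), 0) else 0
  }
  combined <- pg + pp + pf
  post <- exp(combined - max(combined))
  post <- post / sum(post)

  gp <- pg + pp
  tol <- 1e-9 * pmax(1, abs(max(gp)))
  in_set <- gp >= max(gp) - tol
  pair_names <- paste(alleles[pi], alleles[pj], sep = "/")
  ord <- order(-post, pair_names)
  best_idx <- ord[1L]

  cov <- depth_of_coverage(reads, dict, samples = sample, loci = locus)
  mean_depth <- mean(cov$summary$mean_depth)
  flags <- character(0)
  if (mean_depth < min_depth) flags <- c(flags, "low_coverage")
  if (.contamination_signature(gl, ev)) flags <- c(flags, "possible_contamination")

  scores <- data.frame(
    allele1 = alleles[pi], allele2 = alleles[pj],
    log_p_genotype = pg, log_p_phase = pp, log_p_frequency = pf,
    log_p_combined = combined, posterior = post,
    in_matching_set = in_set, stringsAsFactors = FALSE
  )
  structure(list(
    status = "ok", sample = sample, locus = locus,
    best = c(alleles[pi[best_idx]], alleles[pj[best_idx]]),
    best_2digit = truncate_to_2digit(c(alleles[pi[best_idx]], alleles[pj[best_idx]])),
    posterior = post[best_idx],
    matching_set = scores[in_set, c("allele1", "allele2"), drop = FALSE],
    flags = flags, mean_depth = mean_depth, n_reads = nrow(reads),
    scores = scores
  ), class = "hla_call")
}

# Vectorized genotype-concordance scores for all pairs at once.
.pg_all_pairs <- function(gl, lc, pi, pj) {
  np <- length(pi)
  pg <- numeric(np)
  for (exon in names(gl$exons)) {
    amat <- lc$exons[[exon]]$mat
    L <- ncol(amat)
    b1 <- amat[pi, , drop = FALSE]
    b2 <- amat[pj, , drop = FALSE]
    valid <- b1 <= 4L & b2 <= 4L
    g <- matrix(NA_integer_, np, L)
    g[valid] <- .PIDX[cbind(b1[valid], b2[valid])]
    norm <- gl$exons[[exon]]$norm
    colv <- matrix(rep(seq_len(L), each = np), np, L)
    contrib <- matrix(0, np, L)
    contrib[valid] <- norm[cbind(colv[valid], g[valid])]
    pg <- pg + rowSums(contrib)
  }
  pg
}

# Vectorized phase scores for all pairs at once.
.pp_all_pairs <- function(ev, lc, pi, pj, p_err) {
  pp <- numeric(length(pi))
  for (rec in unclass(ev)) {
    amat <- lc$exons[[rec$exon]]$mat
    a1c1 <- amat[pi, rec$col1]; a1c2 <- amat[pi, rec$col2]
    a2c1 <- amat[pj, rec$col1]; a2c2 <- amat[pj, rec$col2]
    defined <- a1c1 <= 4L & a1c2 <= 4L & a2c1 <= 4L & a2c2 <= 4L
    h1 <- (a1c1 - 1L) * 4L + a1c2
    h2 <- (a2c1 - 1L) * 4L + a2c2
    k <- rec$counts[h1] + ifelse(h2 != h1, rec$counts[h2], 0L)
    contrib <- stats::dbinom(k, rec$n, 1 - p_err, log = TRUE)
    pp <- pp + ifelse(defined, contrib, 0)
  }
  pp
}

# Mixture signature (more than two chromosomes present): either >= 2
# well-covered columns showing >= 3 bases each supported by >= 10% of the
# reads at that column, or >= 2 adjacent-site pairs showing >= 3 two-site
# haplotypes each supported by >= 10% of spanning reads (a diploid sample
# explains at most 2 of either).
.contamination_signature <- function(gl, ev, min_col_depth = 10L,
                                     min_share = 0.10, min_multi = 2L) {
  n_cols <- 0L
  for (exon in names(gl$exons)) {
    counts <- gl$exons[[exon]]$counts
    depth <- rowSums(counts)
    ok <- depth >= min_col_depth
    if (!any(ok)) next
    share <- counts[ok, , drop = FALSE] / depth[ok]
    n_cols <- n_cols + sum(rowSums(share >= min_share) >= 3L)
  }
  if (n_cols >= min_multi) return(TRUE)
  n_pairs <- 0L
  for (rec in unclass(ev)) {
    if (rec$n < min_col_depth) next
    if (sum(rec$counts / rec$n >= min_share) >= 3L) n_pairs <- n_pairs + 1L
  }
  n_pairs >= min_multi
}

#' @export
print.hla_call <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("%s %s: no call (%s)\n", x$sample, x$locus,
                paste(x$flags, collapse = ",")))
    return(invisible(x))
  }
  cat(sprintf("%s %s: %s / %s (posterior %.4f, matching set %d pair%s%s)\n",
              x$sample, x$locus, x$best[1L], x$best[2L], x$posterior,
              nrow(x$matching_set), if (nrow(x$matching_set) == 1L) "" else "s",
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Concordance of HLA calls against gold-standard types
#'
#' Compares unordered called pairs with unordered truth pairs per
#' sample-locus under the best-matching assignment of called to true
#' alleles, at both 4-digit and 2-digit resolution.  Accuracy is the number
#' of concordant alleles over the total number of truth alleles compared.
#'
#' @param calls data.frame with columns `sample`, `locus`, `allele1`,
#'   `allele2` (e.g. the `calls` component of [hla_genotype_pool()]).
#' @param truth data.frame with the same columns giving the true pairs.
#' @return List with `four_digit`, `two_digit` (accuracies in `[0, 1]`),
#'   `n_alleles`, `skipped` (call rows without a truth entry), and
#'   `per_call` (per sample-locus concordant-allele counts).
#' @export
evaluate_concordance <- function(calls, truth) {
  need <- c("sample", "locus", "allele1", "allele2")
  stopifnot(all(need %in% names(calls)), all(need %in% names(truth)))
  key_c <- paste(calls$sample, calls$locus)
  key_t <- paste(truth$sample, truth$locus)
  hit <- match(key_c, key_t)
  skipped <- sum(is.na(hit))
  rows <- which(!is.na(hit))
  per_call <- data.frame(
    sample = calls$sample[rows], locus = calls$locus[rows],
    concordant4 = NA_integer_, concordant2 = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (r in seq_along(rows)) {
    i <- rows[r]; j <- hit[i]
    called <- c(calls$allele1[i], calls$allele2[i])
    true <- c(truth$allele1[j], truth$allele2[j])
    per_call$concordant4[r] <- .pair_concordance(called, true)
    per_call$concordant2[r] <- .pair_concordance(truncate_to_2digit(called),
                                                 truncate_to_2digit(true))
  }
  n_alleles <- 2L * length(rows)
  list(
    four_digit = if (n_alleles > 0L) sum(per_call$concordant4) / n_alleles else NA_real_,
    two_digit = if (n_alleles > 0L) sum(per_call$concordant2) / n_alleles else NA_real_,
    n_alleles = n_alleles, skipped = skipped, per_call = per_call
  )
}

# Concordant alleles (0..2) under the better of the two assignments of the
# unordered called pair onto the unordered truth pair.
.pair_concordance <- function(called, true) {
  direct <- sum(called == true)
  crossed <- sum(called == rev(true))
  max(direct, crossed)
}
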
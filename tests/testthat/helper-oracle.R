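# Independent brute-force re-implementation of the pair-scoring model, in
# plain probability space (no log-sum-exp tricks), used as an oracle against
# the package's vectorized log-space caller.  Deliberately written with
# naive loops over reads and pairs.

oracle_bases <- c("A", "C", "G", "T")

oracle_genotypes <- local({
  g <- list()
  for (x in 1:4) for (y in x:4) g[[length(g) + 1L]] <- c(x, y)
  g
})

# P(observed base b | genotype {x,y}) with error prob e.
oracle_obs_prob <- function(b, gt, e) {
  p_one <- function(a) if (a == b) 1 - e else e / 3
  0.5 * p_one(gt[1L]) + 0.5 * p_one(gt[2L])
}

# Per-column genotype probabilities, normalized over the 10 genotypes.
oracle_column_posteriors <- function(reads, exon, column, qual_floor = 5L) {
  probs <- rep(1, 10)
  for (i in seq_len(nrow(reads))) {
    if (reads$exon[i] != exon) next
    off <- column - reads$start[i] + 1L
    if (off < 1L || off > nchar(reads$seq[i])) next
    b <- match(substr(reads$seq[i], off, off), oracle_bases)
    q <- utf8ToInt(substr(reads$qual[i], off, off)) - 33L
    if (is.na(b) || q < qual_floor) next
    e <- 10^(-q / 10)
    for (g in 1:10) probs[g] <- probs[g] * oracle_obs_prob(b, oracle_genotypes[[g]], e)
  }
  probs / sum(probs)
}

oracle_binom_pmf <- function(k, n, p) {
  (factorial(n) / (factorial(k) * factorial(n - k))) * p^k * (1 - p)^(n - k)
}

# Full posterior table over all unordered allele pairs at one locus.
oracle_posteriors <- function(reads, dict, locus, freqs = NULL,
                              population = NULL, p_err = 0.01,
                              qual_floor = 5L, floor = 1e-5) {
  lc <- dict$loci[[locus]]
  alleles <- lc$alleles
  n_all <- length(alleles)
  reads <- reads[reads$locus == locus, , drop = FALSE]

  col_post <- list()
  for (exon in names(lc$exons)) {
    L <- lc$exons[[exon]]$length
    col_post[[exon]] <- lapply(seq_len(L), function(col) {
      oracle_column_posteriors(reads, exon, col, qual_floor)
    })
  }

  base_at <- function(allele, exon, col) {
    match(substr(lc$exons[[exon]]$seq[[allele]], col, col), oracle_bases)
  }

  rows <- list()
  for (i in 1:n_all) for (j in i:n_all) {
    a1 <- alleles[i]; a2 <- alleles[j]
    pg <- 1
    for (exon in names(lc$exons)) {
      for (col in seq_len(lc$exons[[exon]]$length)) {
        b1 <- base_at(a1, exon, col); b2 <- base_at(a2, exon, col)
        if (is.na(b1) || is.na(b2)) next
        gidx <- which(vapply(oracle_genotypes, function(g) {
          all(sort(g) == sort(c(b1, b2)))
        }, logical(1)))
        pg <- pg * col_post[[exon]][[col]][gidx]
      }
    }
    pp <- 1
    for (exon in names(lc$exons)) {
      poly <- lc$exons[[exon]]$polymorphic
      if (length(poly) < 2L) next
      for (t in seq_len(length(poly) - 1L)) {
        c1 <- poly[t]; c2 <- poly[t + 1L]
        hb <- c(base_at(a1, exon, c1), base_at(a1, exon, c2),
                base_at(a2, exon, c1), base_at(a2, exon, c2))
        if (anyNA(hb)) next
        k <- 0L; n <- 0L
        for (r in seq_len(nrow(reads))) {
          if (reads$exon[r] != exon) next
          o1 <- c1 - reads$start[r] + 1L; o2 <- c2 - reads$start[r] + 1L
          if (o1 < 1L || o2 > nchar(reads$seq[r])) next
          rb1 <- match(substr(reads$seq[r], o1, o1), oracle_bases)
          rb2 <- match(substr(reads$seq[r], o2, o2), oracle_bases)
          q1 <- utf8ToInt(substr(reads$qual[r], o1, o1)) - 33L
          q2 <- utf8ToInt(substr(reads$qual[r], o2, o2)) - 33L
          if (is.na(rb1) || is.na(rb2) || q1 < qual_floor || q2 < qual_floor) next
          n <- n + 1L
          match1 <- rb1 == hb[1L] && rb2 == hb[2L]
          match2 <- rb1 == hb[3L] && rb2 == hb[4L]
          if (match1 || match2) k <- k + 1L
        }
        if (n > 0L) pp <- pp * oracle_binom_pmf(k, n, 1 - p_err)
      }
    }
    pf <- 1
    if (!is.null(population)) {
      lookup <- function(a) {
        sub <- freqs$entries[freqs$entries$population == population, ]
        f <- sub$frequency[match(a, sub$allele)]
        if (is.na(f) || f < floor) floor else f
      }
      pf <- lookup(a1) * lookup(a2)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      allele1 = a1, allele2 = a2, p_genotype = pg, p_phase = pp,
      p_frequency = pf, p_combined = pg * pp * pf, stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  tab$posterior <- tab$p_combined / sum(tab$p_combined)
  tab
}
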
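# Read simulator: synthetic barcoded amplicon pools with a complete truth
# table, emulating multiplexed 454-style sequencing of class I HLA exons
# (6 amplicons per sample, ~350 bp reads, ~1% substitution error, per-exon
# read counts in the 50-150 range, optional allelic coverage imbalance and
# cross-sample contamination).  Substitution errors only: homopolymer indel
# errors are not modelled.

#' Simulation configuration
#'
#' Defaults mirror the data regime the caller is designed for: 95 pooled
#' samples, three class I loci with exons 2 and 3 (~270 bp each), 20 known
#' alleles per locus, reads of mean length 350 bp, 1% per-base substitution
#' error, and a mean of 100 reads per exon.  `imbalance` is the expected
#' read-count ratio between the two chromosomes (1 = balanced);
#' `contamination` is the fraction of a sample's reads drawn from another
#' random sample's chromosomes.
#'
#' @param n_samples Number of pooled samples.
#' @param loci Locus identifiers.
#' @param alleles_per_locus Dictionary size per locus (>= 4 when both
#'   `ensure_twin` and `ensure_single_diff` are set).
#' @param exon_lengths Named integer vector of exon alignment lengths.
#' @param poly_density Fraction of columns made polymorphic (0 disables all
#'   variation).
#' @param mean_coverage Mean reads per sample per exon (Poisson).
#' @param imbalance Chromosome coverage ratio r; chromosome 1 of the pair
#'   receives each read with probability `r / (1 + r)`.
#' @param error_rate Per-base substitution error probability.
#' @param read_length_mean,read_length_sd Read length distribution (bp,
#'   normal, truncated below at barcode + primer + 30).
#' @param contamination Fraction of reads replaced by contaminant reads.
#' @param frac_reverse Fraction of reads sequenced in reverse orientation.
#' @param barcode_length Barcode length in bp (6-9).
#' @param primer_length Primer length in bp (18-21).
#' @param rare_twin_share Population frequency share assigned to the
#'   ambiguity twin allele (see [make_toy_dictionary()]).
#' @param freq_shape Gamma shape for drawing skewed allele frequencies.
#' @param ensure_twin,ensure_single_diff Guarantee the two constructed
#'   allele relationships described in [make_toy_dictionary()].
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 95L, loci = c("A", "B", "C"),
                       alleles_per_locus = 20L,
                       exon_lengths = c(exon2 = 270L, exon3 = 276L),
                       poly_density = 0.05, mean_coverage = 100,
                       imbalance = 1, error_rate = 0.01,
                       read_length_mean = 350, read_length_sd = 40,
                       contamination = 0, frac_reverse = 0.5,
                       barcode_length = 8L, primer_length = 20L,
                       rare_twin_share = 0.005, freq_shape = 0.5,
                       ensure_twin = TRUE, ensure_single_diff = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples >= 1L, cfg$poly_density >= 0, cfg$poly_density <= 1,
            cfg$mean_coverage >= 0, cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$imbalance > 0, cfg$contamination >= 0, cfg$contamination <= 1,
            cfg$frac_reverse >= 0, cfg$frac_reverse <= 1,
            cfg$barcode_length >= 6L, cfg$barcode_length <= 9L,
            cfg$primer_length >= 18L, cfg$primer_length <= 21L)
  if ((cfg$ensure_twin || cfg$ensure_single_diff) && cfg$alleles_per_locus < 4L) {
    stop("alleles_per_locus must be >= 4 to embed the constructed allele pairs")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a toy allele dictionary and matching frequency table
#'
#' Builds, per locus, random allele sequences over the configured exon
#' lengths with the configured polymorphic-column density (biallelic
#' columns), embedding two relationships that drive the caller's hardest
#' cases: a *twin* pair -- two alleles identical over the sequenced exons
#' (allele `01:01` and its twin `01:02`), resolvable only by frequency --
#' and a pair differing at exactly one column (`02:01` vs `02:02`, a single
#' diagnostic site).  Population frequencies are drawn from a skewed Gamma
#' and normalized to sum to 1 per locus; the twin is assigned a small fixed
#' share (`rare_twin_share`) so that, as for real rare alleles, the
#' frequency prior points to its common counterpart.
#'
#' @param config A [sim_config()].
#' @return List with `dictionary` (an `hla_dictionary`) and `frequencies`
#'   (an `hla_frequencies` with population `"SIM"`).
#' @export
make_toy_dictionary <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$alleles_per_locus
  sequences <- list()
  freq_rows <- list()
  for (locus in config$loci) {
    names_4d <- .toy_allele_names(locus, n, config)
    exons <- list()
    for (ex in names(config$exon_lengths)) {
      L <- config$exon_lengths[[ex]]
      n_poly <- round(config$poly_density * L)
      if (n_poly > L) stop("polymorphic density implies more columns than length")
      cons <- sample(.BASES, L, replace = TRUE)
      mat <- matrix(rep(cons, each = n), n, L)
      if (n_poly > 0L) {
        poly_cols <- sort(sample.int(L, n_poly))
        for (col in poly_cols) {
          alt <- sample(setdiff(.BASES, cons[col]), 1L)
          repeat {
            pick <- stats::runif(n) < 0.5
            if (any(pick) && !all(pick)) break
          }
          mat[pick, col] <- alt
        }
      }
      exons[[ex]] <- mat
    }
    exons <- .embed_special_pairs(exons, config)
    exons <- .ensure_distinct(exons, config)
    sequences[[locus]] <- lapply(exons, function(mat) {
      stats::setNames(apply(mat, 1L, paste, collapse = ""), names_4d)
    })
    w <- pmax(stats::rgamma(n, shape = config$freq_shape), 1e-4)
    if (config$ensure_twin) w[n] <- config$rare_twin_share * sum(w[-n])
    freq_rows[[locus]] <- data.frame(
      population = "SIM", allele = names_4d, frequency = w / sum(w),
      stringsAsFactors = FALSE
    )
  }
  list(
    dictionary = hla_dictionary(sequences),
    frequencies = hla_frequencies(do.call(rbind, freq_rows))
  )
}

.toy_allele_names <- function(locus, n, config) {
  group <- sprintf("%02d", seq_len(n))
  protein <- rep("01", n)
  if (config$ensure_twin) { group[n] <- "01"; protein[n] <- "02" }
  if (config$ensure_single_diff) { group[3L] <- "02"; protein[3L] <- "02" }
  format_hla_allele(locus, group, protein)
}

# Allele n: exact copy of allele 1 over all exons (the ambiguity twin).
# Allele 3: copy of allele 2 with one polymorphic column flipped (single
# diagnostic difference).
.embed_special_pairs <- function(exons, config) {
  n <- config$alleles_per_locus
  if (config$ensure_twin) {
    for (ex in names(exons)) exons[[ex]][n, ] <- exons[[ex]][1L, ]
  }
  if (config$ensure_single_diff) {
    for (ex in names(exons)) exons[[ex]][3L, ] <- exons[[ex]][2L, ]
    ex1 <- names(exons)[1L]
    poly <- .find_polymorphic(.encode_matrix(exons[[ex1]]))
    if (length(poly) > 0L) {
      col <- poly[1L]
      cur <- exons[[ex1]][3L, col]
      others <- unique(exons[[ex1]][, col])
      alt <- setdiff(others, cur)
      if (length(alt) == 0L) alt <- setdiff(.BASES, cur)[1L]
      exons[[ex1]][3L, col] <- alt[1L]
    }
  }
  exons
}

.encode_matrix <- function(char_mat) {
  matrix(.encode(paste(t(char_mat), collapse = "")),
         nrow(char_mat), ncol(char_mat), byrow = TRUE)
}

# Flip polymorphic columns until no unintended duplicate allele sequences
# remain.  A locus with no polymorphic columns (density 0) legitimately has
# identical alleles and is left untouched.  The constructed special alleles
# (1 and its twin n, the single-diff pair 2/3) are never modified, so their
# designed relationships survive.
.ensure_distinct <- function(exons, config) {
  n <- config$alleles_per_locus
  twin_ok <- function(i, j) config$ensure_twin && i == 1L && j == n
  special <- c(if (config$ensure_twin) c(1L, n),
               if (config$ensure_single_diff) c(2L, 3L))
  ex1 <- names(exons)[1L]
  poly <- .find_polymorphic(.encode_matrix(exons[[ex1]]))
  if (length(poly) == 0L) return(exons)
  iter <- 0L
  repeat {
    sig <- apply(do.call(cbind, exons), 1L, paste, collapse = "")
    dup <- NULL
    for (j in 2:n) {
      for (i in 1:(j - 1L)) {
        if (sig[i] == sig[j] && !twin_ok(i, j)) { dup <- c(i, j); break }
      }
      if (!is.null(dup)) break
    }
    if (is.null(dup)) return(exons)
    iter <- iter + 1L
    if (iter > 1000L) stop("could not make toy alleles pairwise distinct")
    target <- if (!dup[2L] %in% special) dup[2L] else dup[1L]
    if (target %in% special) {
      stop("constructed special alleles collided; use a different seed")
    }
    col <- poly[1L + (iter - 1L) %% length(poly)]
    avoid <- exons[[ex1]][dup, col]
    exons[[ex1]][target, col] <- setdiff(.BASES, avoid)[1L]
  }
}

#' Generate sample barcodes and locus primers for a simulated pool
#'
#' Barcodes are distinct fixed-length random oligos (fixed length makes the
#' manifest trivially prefix-free); primers are random per locus, exon and
#' orientation with pairwise Hamming distance >= 5 so that single-mismatch
#' primer matching stays unambiguous.
#'
#' @param config A [sim_config()].
#' @param dict The dictionary the primers should cover.
#' @return `sim_barcodes`: a `barcode_manifest` for samples
#'   `S001...`; `sim_primers`: a `primer_manifest`.
#' @export
sim_barcodes <- function(config) {
  n <- config$n_samples
  repeat {
    bc <- vapply(seq_len(n), function(i) {
      paste(sample(.BASES, config$barcode_length, replace = TRUE), collapse = "")
    }, character(1))
    if (!anyDuplicated(bc)) break
  }
  barcode_manifest(sprintf("S%03d", seq_len(n)), bc)
}

#' @rdname sim_barcodes
#' @export
sim_primers <- function(config, dict) {
  rows <- expand.grid(locus = dictionary_loci(dict),
                      exon = names(config$exon_lengths),
                      orientation = c("fwd", "rev"),
                      stringsAsFactors = FALSE)
  repeat {
    primers <- vapply(seq_len(nrow(rows)), function(i) {
      paste(sample(.BASES, config$primer_length, replace = TRUE), collapse = "")
    }, character(1))
    d <- utils::combn(primers, 2L, function(p) .hamming(p[1L], p[2L]))
    if (min(d) >= 5L) break
  }
  primer_manifest(rows$locus, rows$exon, rows$orientation, primers)
}

#' Simulate a barcoded amplicon read pool with truth table
#'
#' For every sample, locus and exon the number of reads is Poisson with the
#' configured mean; each read picks a chromosome (respecting the imbalance
#' ratio), a placement uniform among those its insert length allows, and an
#' orientation; barcode and primer are prepended; substitution errors are
#' applied i.i.d. over the whole read; base qualities are set to the Phred
#' equivalent of the configured error rate.  A `contamination` fraction of
#' reads is instead drawn from a random other sample's chromosomes (keeping
#' the host sample's barcode).  All randomness is fixed by the
#' configuration seed; the same configuration yields byte-identical reads
#' and truth tables.
#'
#' @param dict An ungapped `hla_dictionary` (e.g. from
#'   [make_toy_dictionary()]).
#' @param freqs An `hla_frequencies` used to sample truth pairs (population
#'   `"SIM"`) when `truth_pairs` is not supplied.
#' @param barcodes,primers Manifests from [sim_barcodes()] / [sim_primers()].
#' @param config A [sim_config()].
#' @param truth_pairs Optional data.frame `sample`, `locus`, `allele1`,
#'   `allele2` fixing the true genotypes.
#' @return List of class `hla_sim`: `reads` (data.frame `id`, `seq`,
#'   `qual`), `truth` (list with `pairs` and per-read `reads` tables),
#'   plus the `dict`, `freqs`, `barcodes`, `primers`, `config` used.
#' @export
simulate_reads <- function(dict, freqs, barcodes, primers, config,
                           truth_pairs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000003L)
  samples <- barcodes$sample
  loci <- dictionary_loci(dict)
  for (locus in loci) {
    for (ex in names(dict$loci[[locus]]$exons)) {
      if (any(dict$loci[[locus]]$exons[[ex]]$mat > 4L)) {
        stop("simulate_reads requires an ungapped dictionary without unknowns")
      }
    }
  }
  if (is.null(truth_pairs)) {
    truth_pairs <- .sample_truth_pairs(dict, freqs, samples)
  }
  pair_key <- paste(truth_pairs$sample, truth_pairs$locus)
  p_hap1 <- config$imbalance / (1 + config$imbalance)
  q_char <- substr(.int_to_qual(.error_to_phred(config$error_rate)), 1L, 1L)

  read_rows <- list()
  truth_rows <- list()
  serial <- 0L
  for (s in samples) {
    bc <- barcodes$barcode[barcodes$sample == s]
    for (locus in loci) {
      pr <- truth_pairs[match(paste(s, locus), pair_key), ]
      pair <- c(pr$allele1, pr$allele2)
      for (ex in names(dict$loci[[locus]]$exons)) {
        e <- dict$loci[[locus]]$exons[[ex]]
        L <- e$length
        n_reads <- stats::rpois(1L, config$mean_coverage)
        if (n_reads == 0L) next
        contam <- stats::runif(n_reads) < config$contamination
        hap <- ifelse(stats::runif(n_reads) < p_hap1, 1L, 2L)
        src_allele <- pair[hap]
        donor <- rep(NA_character_, n_reads)
        if (any(contam) && length(samples) > 1L) {
          for (i in which(contam)) {
            donor[i] <- sample(setdiff(samples, s), 1L)
            dp <- truth_pairs[match(paste(donor[i], locus), pair_key), ]
            src_allele[i] <- c(dp$allele1, dp$allele2)[hap[i]]
          }
        }
        rev <- stats::runif(n_reads) < config$frac_reverse
        ori <- ifelse(rev, "rev", "fwd")
        plen <- nchar(primers$primer[1L])
        rl <- pmax(round(stats::rnorm(n_reads, config$read_length_mean,
                                      config$read_length_sd)),
                   config$barcode_length + plen + 30L)
        ins_len <- pmin(rl - config$barcode_length - plen, L)
        start <- vapply(ins_len, function(il) {
          if (il >= L) 1L else sample.int(L - il + 1L, 1L)
        }, integer(1))
        ids <- sprintf("%s:%s:%s:%06d", s, locus, ex, serial + seq_len(n_reads))
        serial <- serial + n_reads
        seqs <- character(n_reads)
        for (i in seq_len(n_reads)) {
          segment <- substr(e$seq[[src_allele[i]]], start[i],
                            start[i] + ins_len[i] - 1L)
          insert <- if (rev[i]) .revcomp(segment) else segment
          pm <- primers$primer[primers$locus == locus & primers$exon == ex &
                                 primers$orientation == ori[i]]
          seqs[i] <- .mutate(paste0(bc, pm, insert), config$error_rate)
        }
        read_rows[[length(read_rows) + 1L]] <- data.frame(
          id = ids, seq = seqs,
          qual = strrep(q_char, nchar(seqs)), stringsAsFactors = FALSE
        )
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          id = ids, sample = s, locus = locus, exon = ex, hap = hap,
          allele = src_allele, start = start, insert_len = ins_len,
          strand = ifelse(rev, "-", "+"), contaminant = donor,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  reads <- if (length(read_rows)) do.call(rbind, read_rows) else
    data.frame(id = character(0), seq = character(0), qual = character(0))
  truth_reads <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  structure(list(reads = reads,
                 truth = list(pairs = truth_pairs, reads = truth_reads),
                 dict = dict, freqs = freqs, barcodes = barcodes,
                 primers = primers, config = config),
            class = "hla_sim")
}

.sample_truth_pairs <- function(dict, freqs, samples) {
  rows <- list()
  for (locus in dictionary_loci(dict)) {
    alleles <- dictionary_alleles(dict, locus)
    f <- allele_frequency(freqs, "SIM", alleles)
    for (s in samples) {
      pick <- sort(sample(alleles, 2L, replace = TRUE, prob = f))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, locus = locus, allele1 = pick[1L], allele2 = pick[2L],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# i.i.d. substitution errors over a single sequence string.
.mutate <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  codes <- .encode(seq)
  hit <- which(stats::runif(length(codes)) < error_rate)
  if (length(hit) == 0L) return(seq)
  codes[hit] <- ((codes[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  .decode(codes)
}

#' Run the full simulation in one call
#'
#' Convenience wrapper: builds the toy dictionary and frequencies, barcode
#' and primer manifests, and the simulated read pool, all from one
#' configuration.
#'
#' @param config A [sim_config()].
#' @return An `hla_sim` (see [simulate_reads()]).
#' @export
sim_hla_pool <- function(config) {
  toy <- make_toy_dictionary(config)
  set.seed(config$seed + 2000003L)
  barcodes <- sim_barcodes(config)
  primers <- sim_primers(config, toy$dictionary)
  simulate_reads(toy$dictionary, toy$frequencies, barcodes, primers, config)
}

#' @export
print.hla_sim <- function(x, ...) {
  cat(sprintf("Simulated pool: %d reads, %d samples, loci %s (seed %d)\n",
              nrow(x$reads), x$config$n_samples,
              paste(x$config$loci, collapse = ","), x$config$seed))
  invisible(x)
}

#' Write simulator truth placements as SAM
#'
#' Emits one alignment record per simulated read against the dictionary's
#' ungapped consensus references (`<locus>|<exon>`), using the simulator's
#' true placements; reverse-orientation reads get flag 16 with the
#' reference-oriented insert in the SEQ field.  Round-tripping this file
#' through [ingest_alignments()] reproduces the truth placements.
#'
#' @param sim An `hla_sim`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(sim, path) {
  dict <- sim$dict
  hdr <- c("@HD\tVN:1.6\tSO:unsorted")
  for (locus in dictionary_loci(dict)) {
    for (ex in names(dict$loci[[locus]]$exons)) {
      hdr <- c(hdr, sprintf("@SQ\tSN:%s|%s\tLN:%d", locus, ex,
                            dict$loci[[locus]]$exons[[ex]]$length))
    }
  }
  tr <- sim$truth$reads
  plen <- nchar(sim$primers$primer[1L])
  bclen <- sim$config$barcode_length
  recs <- character(nrow(tr))
  seq_by_id <- stats::setNames(sim$reads$seq, sim$reads$id)
  qual_by_id <- stats::setNames(sim$reads$qual, sim$reads$id)
  for (i in seq_len(nrow(tr))) {
    full <- seq_by_id[[tr$id[i]]]
    q <- qual_by_id[[tr$id[i]]]
    insert <- substr(full, bclen + plen + 1L, nchar(full))
    qins <- substr(q, bclen + plen + 1L, nchar(q))
    if (tr$strand[i] == "-") {
      insert <- .revcomp(insert)
      qins <- .revstring(qins)
    }
    flag <- if (tr$strand[i] == "-") 16L else 0L
    recs[i] <- paste(tr$id[i], flag, paste0(tr$locus[i], "|", tr$exon[i]),
                     tr$start[i], 60L, paste0(nchar(insert), "M"),
                     "*", 0L, 0L, insert, qins, sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
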
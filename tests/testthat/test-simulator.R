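test_that("the same seed reproduces reads and truth byte for byte", {
  cfg <- sim_config(n_samples = 5, mean_coverage = 15, seed = 7)
  s1 <- sim_hla_pool(cfg)
  s2 <- sim_hla_pool(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$dict$loci$A$exons$exon2$seq, s2$dict$loci$A$exons$exon2$seq)
  s3 <- sim_hla_pool(sim_config(n_samples = 5, mean_coverage = 15, seed = 8))
  expect_false(identical(s1$reads, s3$reads))
})

test_that("toy dictionaries embed the twin and single-diff allele pairs", {
  cfg <- sim_config(n_samples = 2, seed = 14)
  toy <- make_toy_dictionary(cfg)
  for (locus in cfg$loci) {
    lc <- toy$dictionary$loci[[locus]]
    alleles <- lc$alleles
    n <- length(alleles)
    # twin: last allele identical to the first over all exons, same 2-digit group
    for (ex in names(lc$exons)) {
      expect_identical(unname(lc$exons[[ex]]$seq[[alleles[1]]]),
                       unname(lc$exons[[ex]]$seq[[alleles[n]]]))
    }
    expect_equal(truncate_to_2digit(alleles[1]), truncate_to_2digit(alleles[n]))
    # single diagnostic column between alleles 2 and 3
    diffs <- sum(vapply(names(lc$exons), function(ex) {
      sum(lc$exons[[ex]]$mat[2, ] != lc$exons[[ex]]$mat[3, ])
    }, numeric(1)))
    expect_equal(diffs, 1)
    # all other alleles pairwise distinct
    sig <- vapply(alleles, function(a) {
      paste(vapply(names(lc$exons), function(ex) lc$exons[[ex]]$seq[[a]],
                   character(1)), collapse = "")
    }, character(1))
    expect_equal(anyDuplicated(sig[-n]), 0L)
  }
})

test_that("generated frequencies are normalized and the twin is rare", {
  cfg <- sim_config(n_samples = 2, seed = 25)
  toy <- make_toy_dictionary(cfg)
  for (locus in cfg$loci) {
    sub <- toy$frequencies$entries[
      allele_locus(toy$frequencies$entries$allele) == locus, ]
    expect_equal(sum(sub$frequency), 1, tolerance = 1e-9)
    twin <- dictionary_alleles(toy$dictionary, locus)[cfg$alleles_per_locus]
    expect_lt(sub$frequency[sub$allele == twin], 0.01)
  }
})

test_that("zero polymorphic density yields an invariant locus", {
  cfg <- sim_config(n_samples = 2, loci = "A", poly_density = 0,
                    ensure_twin = FALSE, ensure_single_diff = FALSE, seed = 3)
  toy <- make_toy_dictionary(cfg)
  expect_length(polymorphic_columns(toy$dictionary, "A", "exon2"), 0L)
})

test_that("error-free reads reproduce true haplotypes; errors hit at the set rate", {
  cfg0 <- sim_config(n_samples = 4, mean_coverage = 20, error_rate = 0, seed = 5)
  sim0 <- sim_hla_pool(cfg0)
  tr <- sim0$truth$reads
  plen <- nchar(sim0$primers$primer[1])
  for (i in sample(nrow(tr), 40)) {
    e <- sim0$dict$loci[[tr$locus[i]]]$exons[[tr$exon[i]]]
    segment <- substr(e$seq[[tr$allele[i]]], tr$start[i],
                      tr$start[i] + tr$insert_len[i] - 1L)
    insert <- substr(sim0$reads$seq[match(tr$id[i], sim0$reads$id)],
                     cfg0$barcode_length + plen + 1L, 10000L)
    if (tr$strand[i] == "-") {
      insert <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(insert)))
    }
    expect_identical(insert, segment)
  }
  # empirical error rate within 3 standard errors over >= 1e5 bases
  cfg1 <- sim_config(n_samples = 10, mean_coverage = 40, error_rate = 0.01,
                     seed = 6)
  sim1 <- sim_hla_pool(cfg1)
  tr1 <- sim1$truth$reads
  n_bases <- 0L; n_err <- 0L
  idx <- match(tr1$id, sim1$reads$id)
  plen1 <- nchar(sim1$primers$primer[1])
  for (i in seq_len(nrow(tr1))) {
    e <- sim1$dict$loci[[tr1$locus[i]]]$exons[[tr1$exon[i]]]
    segment <- substr(e$seq[[tr1$allele[i]]], tr1$start[i],
                      tr1$start[i] + tr1$insert_len[i] - 1L)
    insert <- substr(sim1$reads$seq[idx[i]], cfg1$barcode_length + plen1 + 1L,
                     10000L)
    if (tr1$strand[i] == "-") {
      insert <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(insert)))
    }
    n_bases <- n_bases + nchar(segment)
    n_err <- n_err + sum(utf8ToInt(insert) != utf8ToInt(segment))
  }
  expect_gte(n_bases, 1e5)
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(n_err / n_bases - 0.01), 3 * se)
})

test_that("haplotype sampling is balanced at imbalance 1 and skewed at 9", {
  cfg <- sim_config(n_samples = 30, mean_coverage = 30, error_rate = 0, seed = 9)
  sim <- sim_hla_pool(cfg)
  tr <- sim$truth$reads[is.na(sim$truth$reads$contaminant), ]
  # only heterozygous sample-loci carry haplotype information
  n1 <- sum(tr$hap == 1); n <- nrow(tr)
  p <- binom.test(n1, n, 0.5)$p.value
  expect_gt(p, 0.001)
  cfg9 <- sim_config(n_samples = 30, mean_coverage = 30, imbalance = 9, seed = 9)
  sim9 <- sim_hla_pool(cfg9)
  frac1 <- mean(sim9$truth$reads$hap == 1)
  expect_gt(frac1, 0.85)
  expect_lt(frac1, 0.95)
})

test_that("read length and coverage track their configured means", {
  cfg <- sim_config(n_samples = 10, mean_coverage = 60, seed = 77)
  sim <- sim_hla_pool(cfg)
  # raw (pre-truncation) read length is normal(350, 40); emitted reads are
  # capped at barcode + primer + amplicon, so check the cap and the count
  lens <- nchar(sim$reads$seq)
  cap2 <- cfg$barcode_length + cfg$primer_length + 270L
  cap3 <- cfg$barcode_length + cfg$primer_length + 276L
  expect_true(all(lens <= cap3))
  expect_gt(mean(lens %in% c(cap2, cap3)), 0.5)  # most reads span the exon
  n_cells <- cfg$n_samples * length(cfg$loci) * 2
  mean_reads <- nrow(sim$reads) / n_cells
  se <- sqrt(60 / n_cells)
  expect_lt(abs(mean_reads - 60), 4 * se)
})

test_that("contaminated pools show extra haplotypes and get flagged", {
  cfg <- sim_config(n_samples = 6, mean_coverage = 60, contamination = 0.5,
                    seed = 5)
  sim <- sim_hla_pool(cfg)
  expect_gt(sum(!is.na(sim$truth$reads$contaminant)), 0L)
  res <- hla_genotype_pool(sim$reads, sim$barcodes, sim$primers, sim$dict,
                           sim$freqs, population = "SIM")
  expect_gt(mean(grepl("possible_contamination", res$calls$flags)), 0.5)
  # a clean pool under the same seed does not fire the flag
  cfg0 <- sim_config(n_samples = 6, mean_coverage = 60, contamination = 0,
                     seed = 5)
  sim0 <- sim_hla_pool(cfg0)
  res0 <- hla_genotype_pool(sim0$reads, sim0$barcodes, sim0$primers, sim0$dict,
                            sim0$freqs, population = "SIM")
  expect_equal(sum(grepl("possible_contamination", res0$calls$flags)), 0L)
})
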
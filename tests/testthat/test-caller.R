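test_that("frequency priors multiply allele frequencies with a floor", {
  ft <- hla_frequencies(data.frame(
    population = "CAU", allele = c("A*02:01", "A*02:07"),
    frequency = c(0.10, 0.05)
  ))
  expect_equal(p_frequency("A*02:01", "A*02:07", ft, "CAU"), log(0.005))
  expect_equal(p_frequency("A*02:01", "A*02:01", ft, "CAU"), log(0.01))
  expect_equal(p_frequency("A*02:01", "A*99:99", ft, "CAU"), log(0.1 * 1e-5))
  # unspecified ancestry: uniform prior, constant in log space
  expect_equal(p_frequency("A*02:01", "A*02:07", NULL, NULL), 0)
  # optional Hardy-Weinberg factor
  expect_equal(p_frequency("A*02:01", "A*02:07", ft, "CAU", hwe = TRUE),
               log(2 * 0.005))
  expect_equal(p_frequency("A*02:01", "A*02:01", ft, "CAU", hwe = TRUE),
               log(0.01))
})

test_that("posteriors are normalized over all pairs, up to 50 alleles", {
  for (n_alleles in c(4L, 20L, 50L)) {
    cfg <- sim_config(n_samples = 1, loci = "A", alleles_per_locus = n_alleles,
                      mean_coverage = 25, seed = n_alleles)
    sim <- sim_hla_pool(cfg)
    dm <- demultiplex(sim$reads, sim$barcodes)
    la <- assign_locus(dm$assigned, sim$primers)
    pa <- plumbing_align(la$assigned, sim$dict)
    cl <- call_locus(pa$reads, sim$dict, "A", sim$freqs, "SIM")
    expect_equal(nrow(cl$scores), n_alleles * (n_alleles + 1) / 2)
    expect_equal(sum(cl$scores$posterior), 1, tolerance = 1e-9)
  }
})

test_that("indistinguishable alleles form the matching set; frequency picks", {
  # P and Q identical over the sequenced exon; f(P) >> f(Q)
  dict <- hla_dictionary(list(A = list(exon2 = c(
    "A*01:01" = "AAATTGAAAAAC",
    "A*01:02" = "AAATTGAAAAAC",
    "A*02:01" = "AACTTTAAGAAT"
  ))))
  ft <- hla_frequencies(data.frame(
    population = "P", allele = c("A*01:01", "A*01:02", "A*02:01"),
    frequency = c(0.2, 0.01, 0.5)
  ))
  reads <- reads_from_pair(dict, "A", c("A*01:01", "A*01:01"), n_per_hap = 10)
  cl <- call_locus(reads, dict, "A", ft, "P")
  ms <- paste(cl$matching_set$allele1, cl$matching_set$allele2, sep = "/")
  expect_setequal(ms, c("A*01:01/A*01:01", "A*01:01/A*01:02", "A*01:02/A*01:02"))
  expect_equal(cl$best, c("A*01:01", "A*01:01"))
  expect_true(all(paste(cl$best, collapse = "/") %in% ms))
})

test_that("a single diagnostic column separates near-identical alleles", {
  # two alleles differing at exactly one position (T>C pattern)
  dict <- hla_dictionary(list(C = list(exon2 = c(
    "C*02:02" = "TTGACCAGTAGG",
    "C*02:10" = "TTGATCAGTAGG",
    "C*05:01" = "AAGACCTGTACG"
  ))))
  reads <- reads_from_pair(dict, "C", c("C*02:10", "C*02:10"), n_per_hap = 12)
  cl <- call_locus(reads, dict, "C")
  expect_equal(cl$best, c("C*02:10", "C*02:10"))
  # the T-bearing homozygote beats the C-bearing one decisively
  s <- cl$scores
  lp <- function(a1, a2) s$log_p_combined[s$allele1 == a1 & s$allele2 == a2]
  expect_gt(lp("C*02:10", "C*02:10"), lp("C*02:02", "C*02:02") + 10)
})

test_that("full posterior table matches the brute-force oracle", {
  cfg <- sim_config(n_samples = 1, loci = "A", alleles_per_locus = 4,
                    exon_lengths = c(exon2 = 40L, exon3 = 30L),
                    poly_density = 0.15, mean_coverage = 15,
                    read_length_mean = 80, read_length_sd = 15, seed = 61)
  sim <- sim_hla_pool(cfg)
  dm <- demultiplex(sim$reads, sim$barcodes)
  la <- assign_locus(dm$assigned, sim$primers)
  pa <- plumbing_align(la$assigned, sim$dict)
  reads <- misalignment_filter(pa$reads, sim$dict)$reads
  expect_lte(nrow(reads), 50L)
  cl <- call_locus(reads, sim$dict, "A", sim$freqs, "SIM")
  oracle <- oracle_posteriors(reads, sim$dict, "A", sim$freqs, "SIM")
  key_got <- paste(cl$scores$allele1, cl$scores$allele2)
  key_want <- paste(oracle$allele1, oracle$allele2)
  expect_setequal(key_got, key_want)
  got <- cl$scores$posterior[match(key_want, key_got)]
  expect_equal(got, oracle$posterior, tolerance = 1e-9)
})

test_that("posteriors are invariant under constant rescaling of components", {
  dict <- tiny_dictionary()
  reads <- reads_from_pair(dict, "A", c("A*01:01", "A*03:01"), n_per_hap = 6)
  cl <- call_locus(reads, dict, "A")
  shifted <- cl$scores$log_p_genotype + 5 + cl$scores$log_p_phase - 2 +
    cl$scores$log_p_frequency + 0.7
  post <- exp(shifted - max(shifted)); post <- post / sum(post)
  expect_equal(post, cl$scores$posterior, tolerance = 1e-12)
})

test_that("with uniform frequencies the best guess tracks genotype and phase", {
  cfg <- sim_config(n_samples = 1, loci = "A", mean_coverage = 40, seed = 19)
  sim <- sim_hla_pool(cfg)
  dm <- demultiplex(sim$reads, sim$barcodes)
  la <- assign_locus(dm$assigned, sim$primers)
  pa <- plumbing_align(la$assigned, sim$dict)
  cl_unif <- call_locus(pa$reads, sim$dict, "A")
  s <- cl_unif$scores
  gp <- s$log_p_genotype + s$log_p_phase
  expect_equal(sort(unname(cl_unif$best)),
               sort(unname(c(s$allele1[which.max(gp)], s$allele2[which.max(gp)]))))
})

test_that("zero kept reads yield an explicit no-call, not an error", {
  dict <- tiny_dictionary()
  cl <- call_locus(tiny_dictionary_empty_reads(), dict, "A", sample = "s9")
  expect_equal(cl$status, "no_call")
  expect_true("no_reads" %in% cl$flags)
  expect_output(print(cl), "no call")
})

test_that("low coverage is flagged below 20 mean reads", {
  dict <- tiny_dictionary()
  few <- reads_from_pair(dict, "A", c("A*01:01", "A*02:01"), n_per_hap = 4)
  many <- reads_from_pair(dict, "A", c("A*01:01", "A*02:01"), n_per_hap = 15)
  expect_true("low_coverage" %in% call_locus(few, dict, "A")$flags)
  expect_false("low_coverage" %in% call_locus(many, dict, "A")$flags)
})

test_that("concordance counts best-matched alleles at both resolutions", {
  truth <- data.frame(sample = "s", locus = "A",
                      allele1 = "A*02:01", allele2 = "A*02:07")
  exact <- data.frame(sample = "s", locus = "A",
                      allele1 = "A*02:07", allele2 = "A*02:01")  # order-free
  hom <- data.frame(sample = "s", locus = "A",
                    allele1 = "A*02:01", allele2 = "A*02:01")
  cc1 <- evaluate_concordance(exact, truth)
  expect_equal(cc1$four_digit, 1)
  expect_equal(cc1$two_digit, 1)
  cc2 <- evaluate_concordance(hom, truth)
  expect_equal(cc2$four_digit, 0.5)
  expect_equal(cc2$two_digit, 1)
  # missing truth entries are skipped and counted
  extra <- rbind(exact, data.frame(sample = "s2", locus = "A",
                                   allele1 = "A*01:01", allele2 = "A*01:01"))
  cc3 <- evaluate_concordance(extra, truth)
  expect_equal(cc3$skipped, 1L)
  expect_equal(cc3$n_alleles, 2L)
})

test_that("concordance agrees with the simulator's own bookkeeping", {
  cfg <- sim_config(n_samples = 6, mean_coverage = 40, seed = 33)
  sim <- sim_hla_pool(cfg)
  res <- hla_genotype_pool(sim$reads, sim$barcodes, sim$primers, sim$dict,
                           sim$freqs, population = "SIM")
  cc <- evaluate_concordance(res$calls, sim$truth$pairs)
  # independent tally straight off the two tables
  manual <- 0L
  for (i in seq_len(nrow(res$calls))) {
    j <- which(sim$truth$pairs$sample == res$calls$sample[i] &
                 sim$truth$pairs$locus == res$calls$locus[i])
    called <- c(res$calls$allele1[i], res$calls$allele2[i])
    true <- c(sim$truth$pairs$allele1[j], sim$truth$pairs$allele2[j])
    manual <- manual + max(sum(called == true), sum(called == rev(true)))
  }
  expect_equal(cc$four_digit, manual / (2 * nrow(res$calls)))
})
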
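Package: hlacaller
Title: Classical HLA Class I Typing from Multiplexed Amplicon Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls 4-digit classical HLA class I genotypes (HLA-A, -B, -C)
    from pooled amplicon sequencing reads covering exons 2 and 3.  Reads are
    demultiplexed by molecular barcode, assigned to a locus by primer
    sequence, aligned against an IMGT/HLA-style allele dictionary, and
    cleaned with a SNP-homology misalignment filter.  For every candidate
    pair of 4-digit alleles the caller combines per-site diploid genotype
    likelihoods, a binomial phase-consistency score over adjacent
    polymorphic sites, and population allele-frequency priors into a
    normalized posterior, reporting both the full matching set of compatible
    allele pairs and a frequency-resolved best guess.  A configurable read
    simulator with a complete truth table makes the whole pipeline testable
    without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    S4Vectors,
    Biostrings,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
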
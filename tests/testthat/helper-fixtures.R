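# Small in-code fixtures shared across tests.

# A hand-built single-locus dictionary: 4 alleles over one 12 bp exon.
# Polymorphic columns: 3 (A/C), 6 (G/T), 9 (A/G), 12 (C/T).
tiny_dictionary <- function() {
  hla_dictionary(list(
    A = list(exon2 = c(
      "A*01:01" = "AAATTGAAAAAC",
      "A*02:01" = "AACTTTAAGAAT",
      "A*03:01" = "AAATTTAAGAAC",
      "A*04:01" = "AACTTGAAAAAT"
    ))
  ))
}

# Assigned-read rows built by hand (reference-oriented, alignment space).
assigned_read <- function(seq, start = 1L, qual = 30L, locus = "A",
                          exon = "exon2", sample = "s1",
                          id = paste0(sample, ":r", start, ":", seq)) {
  data.frame(
    read_id = id, sample = sample, locus = locus, exon = exon,
    start = as.integer(start), seq = seq,
    qual = strrep(intToUtf8(qual + 33L), nchar(seq)), strand = "+",
    stringsAsFactors = FALSE
  )
}

# Zero-row assigned-read table with the right columns.
tiny_dictionary_empty_reads <- function() assigned_read("A")[0, ]

# Error-free reads copied from a dictionary allele's exon sequence.
reads_from_allele <- function(dict, locus, allele, n = 10L, exon = NULL,
                              sample = "s1", qual = 30L) {
  lc <- dict$loci[[locus]]
  exons <- if (is.null(exon)) names(lc$exons) else exon
  do.call(rbind, lapply(exons, function(ex) {
    seq <- unname(lc$exons[[ex]]$seq[[allele]])
    do.call(rbind, lapply(seq_len(n), function(i) {
      assigned_read(seq, start = 1L, qual = qual, locus = locus, exon = ex,
                    sample = sample,
                    id = sprintf("%s:%s:%s:%s:%d", sample, locus, ex, allele, i))
    }))
  }))
}

# Reads from both alleles of a diploid pair, n per chromosome.
reads_from_pair <- function(dict, locus, pair, n_per_hap = 10L, ...) {
  rbind(reads_from_allele(dict, locus, pair[1L], n = n_per_hap, ...),
        reads_from_allele(dict, locus, pair[2L], n = n_per_hap, ...))
}
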
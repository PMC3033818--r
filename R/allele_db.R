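# Allele dictionary: per-locus multiple alignments of known HLA allele
# sequences over the amplified exons, plus the polymorphic-column index the
# phasing and misalignment-filter stages depend on.

#' Build an HLA allele dictionary from aligned sequences
#'
#' The dictionary holds, for each locus, the gapped sequences of every known
#' allele over each sequenced exon (all alleles at one locus share the same
#' alignment length per exon), a per-column reference-position label, and the
#' sorted index of polymorphic columns -- alignment columns at which at least
#' two alleles carry distinct non-gap bases.
#'
#' Alignment columns are indexed 1-based internally; externally reported
#' positions use the per-column reference labels, which are carried as opaque
#' annotations (e.g. genomic coordinates) rather than interpreted.
#'
#' @param sequences Nested list: `sequences[[locus]][[exon]]` is a named
#'   character vector of equal-length gapped sequences (alphabet
#'   `A,C,G,T,-,N`), names being full 4-digit allele names such as
#'   `"A*02:07"`.
#' @param positions Optional nested list parallel to `sequences` giving, per
#'   locus and exon, a character vector of reference position labels (one per
#'   alignment column).  Defaults to `"1" ... "L"`.
#' @return An object of class `hla_dictionary`.
#' @export
hla_dictionary <- function(sequences, positions = NULL) {
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  loci <- names(sequences)
  if (is.null(loci) || anyNA(loci) || any(loci == "")) {
    stop("sequences must be a named list of loci")
  }
  out <- list(loci = list())
  for (locus in loci) {
    exons <- sequences[[locus]]
    exon_ids <- names(exons)
    if (is.null(exon_ids) || any(exon_ids == "")) {
      stop("locus ", locus, ": exons must be named")
    }
    allele_names <- names(exons[[1L]])
    if (anyDuplicated(allele_names)) {
      stop("locus ", locus, ": duplicate allele name: ",
           allele_names[duplicated(allele_names)][1L])
    }
    parsed <- parse_hla_allele(allele_names)
    if (any(parsed$locus != locus)) {
      stop("locus ", locus, ": allele named for a different locus: ",
           allele_names[parsed$locus != locus][1L])
    }
    if (anyNA(parsed$protein)) {
      stop("locus ", locus, ": dictionary alleles must be 4-digit names")
    }
    locus_entry <- list(alleles = allele_names, exons = list())
    for (ex in exon_ids) {
      seqs <- exons[[ex]]
      if (!identical(sort(names(seqs)), sort(allele_names))) {
        stop("locus ", locus, ": exon ", ex,
             " does not list the same alleles as the other exons")
      }
      seqs <- seqs[allele_names]
      lens <- nchar(seqs)
      if (length(unique(lens)) != 1L) {
        off <- names(seqs)[lens != lens[1L]][1L]
        stop("locus ", locus, " exon ", ex,
             ": gapped length mismatch for allele ", off)
      }
      L <- lens[[1L]]
      mat <- matrix(NA_integer_, length(seqs), L,
                    dimnames = list(allele_names, NULL))
      for (i in seq_along(seqs)) mat[i, ] <- .encode(seqs[[i]])
      if (anyNA(mat)) {
        bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
        stop("locus ", locus, " exon ", ex, ": illegal character in allele ",
             allele_names[bad[["row"]]], " at column ", bad[["col"]])
      }
      labels <- positions[[locus]][[ex]]
      if (is.null(labels)) labels <- as.character(seq_len(L))
      if (length(labels) != L) {
        stop("locus ", locus, " exon ", ex,
             ": position labels must have one entry per alignment column")
      }
      locus_entry$exons[[ex]] <- .build_exon(seqs, mat, labels)
    }
    out$loci[[locus]] <- locus_entry
  }
  structure(out, class = "hla_dictionary")
}

.build_exon <- function(seqs, mat, labels) {
  poly <- .find_polymorphic(mat)
  cons <- .exon_consensus(mat)
  list(
    seq = seqs,
    mat = mat,
    length = ncol(mat),
    positions = as.character(labels),
    polymorphic = poly,
    consensus = cons$string,
    consensus_codes = cons$codes,
    # map from ungapped reference position (1-based) -> alignment column
    ref_to_col = which(cons$codes != .GAP_CODE)
  )
}

# Columns where >= 2 distinct bases (A/C/G/T only) occur among the alleles.
.find_polymorphic <- function(mat) {
  n_distinct <- apply(mat, 2L, function(col) length(unique(col[col <= 4L])))
  sort(which(n_distinct >= 2L))
}

# Majority base per column (gap only where all alleles are gapped).
.exon_consensus <- function(mat) {
  codes <- apply(mat, 2L, function(col) {
    known <- col[col <= 4L]
    if (length(known) == 0L) {
      if (all(col == .GAP_CODE)) .GAP_CODE else .UNKNOWN_CODE
    } else {
      as.integer(which.max(tabulate(known, 4L)))
    }
  })
  list(codes = as.integer(codes), string = .decode(codes))
}

#' @export
print.hla_dictionary <- function(x, ...) {
  cat("HLA allele dictionary\n")
  for (locus in names(x$loci)) {
    lc <- x$loci[[locus]]
    npoly <- sum(vapply(lc$exons, function(e) length(e$polymorphic), integer(1)))
    cat(sprintf("  %s: %d alleles, exons %s, %d polymorphic columns\n",
                locus, length(lc$alleles),
                paste(names(lc$exons), collapse = "+"), npoly))
  }
  invisible(x)
}

#' List loci, alleles or polymorphic columns of a dictionary
#'
#' @param dict An `hla_dictionary`.
#' @param locus Locus identifier.
#' @param exon Optional exon identifier; if omitted,
#'   `polymorphic_columns` returns a data.frame over all exons.
#' @return `dictionary_loci`: character vector of loci.
#'   `dictionary_alleles`: character vector of allele names at `locus`.
#'   `polymorphic_columns`: integer vector of 1-based alignment columns (or a
#'   data.frame with columns `exon`, `column` when `exon` is omitted).
#' @export
dictionary_loci <- function(dict) names(dict$loci)

#' @rdname dictionary_loci
#' @export
dictionary_alleles <- function(dict, locus) {
  .get_locus(dict, locus)$alleles
}

#' @rdname dictionary_loci
#' @export
polymorphic_columns <- function(dict, locus, exon = NULL) {
  lc <- .get_locus(dict, locus)
  if (!is.null(exon)) {
    return(.get_exon(lc, locus, exon)$polymorphic)
  }
  do.call(rbind, lapply(names(lc$exons), function(ex) {
    p <- lc$exons[[ex]]$polymorphic
    if (length(p) == 0L) return(NULL)
    data.frame(exon = ex, column = p, stringsAsFactors = FALSE)
  }))
}

.get_locus <- function(dict, locus) {
  lc <- dict$loci[[locus]]
  if (is.null(lc)) stop("unknown locus: ", locus)
  lc
}

.get_exon <- function(locus_entry, locus, exon) {
  e <- locus_entry$exons[[exon]]
  if (is.null(e)) stop("unknown exon ", exon, " at locus ", locus)
  e
}

#' Read an allele dictionary from aligned FASTA files
#'
#' Expects one aligned multi-FASTA per locus and exon, named
#' `<LOCUS>.<exon>.fasta`, with full allele names as headers, plus an
#' optional sidecar `<LOCUS>.<exon>.positions.tsv` (columns `column`,
#' `label`) mapping alignment columns to reference position labels.
#'
#' @param dir Directory containing the FASTA files.
#' @return An `hla_dictionary`.
#' @export
read_allele_dictionary <- function(dir) {
  files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  if (length(files) == 0L) stop("no .fasta files found in ", dir)
  sequences <- list()
  positions <- list()
  for (f in files) {
    parts <- strsplit(sub("\\.fasta$", "", basename(f)), ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("dictionary FASTA files must be named <LOCUS>.<exon>.fasta: ",
           basename(f))
    }
    locus <- parts[1L]; exon <- parts[2L]
    ss <- Biostrings::readBStringSet(f)
    seqs <- toupper(as.character(ss))
    names(seqs) <- names(ss)
    sequences[[locus]][[exon]] <- seqs
    pf <- file.path(dir, paste0(locus, ".", exon, ".positions.tsv"))
    if (file.exists(pf)) {
      tab <- utils::read.delim(pf, stringsAsFactors = FALSE)
      positions[[locus]][[exon]] <- tab$label[order(tab$column)]
    }
  }
  hla_dictionary(sequences, positions)
}

#' Write an allele dictionary to aligned FASTA files
#'
#' Inverse of [read_allele_dictionary()]: writes one multi-FASTA and one
#' position-label sidecar TSV per locus and exon into `dir`.
#'
#' @param dict An `hla_dictionary`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_allele_dictionary <- function(dict, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (locus in names(dict$loci)) {
    for (exon in names(dict$loci[[locus]]$exons)) {
      e <- dict$loci[[locus]]$exons[[exon]]
      ss <- Biostrings::BStringSet(e$seq)
      Biostrings::writeXStringSet(ss, file.path(dir, paste0(locus, ".", exon, ".fasta")))
      utils::write.table(
        data.frame(column = seq_len(e$length), label = e$positions),
        file.path(dir, paste0(locus, ".", exon, ".positions.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }
  invisible(dir)
}

#' Export ungapped per-exon consensus references
#'
#' Writes one FASTA of ungapped consensus sequences (headers
#' `<locus>|<exon>`) for use as an alignment reference with any external
#' aligner; [ingest_alignments()] resolves these names back to dictionary
#' coordinates.
#'
#' @param dict An `hla_dictionary`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(dict, path) {
  seqs <- character(0)
  for (locus in names(dict$loci)) {
    for (exon in names(dict$loci[[locus]]$exons)) {
      e <- dict$loci[[locus]]$exons[[exon]]
      ungapped <- .decode(e$consensus_codes[e$consensus_codes != .GAP_CODE])
      seqs[paste0(locus, "|", exon)] <- ungapped
    }
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Population allele frequencies

#' Weighted average of allele-frequency estimates
#'
#' Combines frequency estimates from multiple typing studies of the same
#' population into a single estimate, weighting each source by its sample
#' size: `sum(f_i * n_i) / sum(n_i)`.
#'
#' @param frequencies Numeric vector of frequency estimates in `[0, 1]`.
#' @param sample_sizes Positive numeric vector of source sample sizes.
#' @return The weighted mean frequency.
#' @examples
#' weighted_frequency(c(0.10, 0.20), c(100, 300))  # 0.175
#' @export
weighted_frequency <- function(frequencies, sample_sizes) {
  if (length(frequencies) == 0L) {
    stop("no frequency sources for this allele", call. = FALSE)
  }
  stopifnot(length(frequencies) == length(sample_sizes),
            all(sample_sizes > 0), all(frequencies >= 0))
  sum(frequencies * sample_sizes) / sum(sample_sizes)
}

#' Construct a population allele-frequency table
#'
#' @param entries data.frame with columns `population`, `allele`,
#'   `frequency` (one row per population/allele; frequencies in `[0, 1]`,
#'   per-population-and-locus sums may be below 1 for partial tables).
#' @return An object of class `hla_frequencies`.
#' @export
hla_frequencies <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("population", "allele", "frequency") %in% names(entries)))
  if (any(entries$frequency < 0)) stop("negative allele frequency")
  parsed <- parse_hla_allele(entries$allele)
  key <- paste(entries$population, entries$allele)
  if (anyDuplicated(key)) {
    stop("duplicate (population, allele) entry: ", key[duplicated(key)][1L])
  }
  sums <- tapply(entries$frequency, paste(entries$population, parsed$locus), sum)
  if (any(sums > 1 + 1e-6)) {
    stop("frequencies sum to > 1 for ", names(sums)[which(sums > 1 + 1e-6)[1L]])
  }
  structure(
    list(entries = entries[c("population", "allele", "frequency")],
         populations = sort(unique(entries$population))),
    class = "hla_frequencies"
  )
}

#' @export
print.hla_frequencies <- function(x, ...) {
  cat(sprintf("HLA allele frequencies: %d entries, populations: %s\n",
              nrow(x$entries), paste(x$populations, collapse = ", ")))
  invisible(x)
}

#' Read a population allele-frequency table
#'
#' Reads a TSV with columns `population`, `allele`, `frequency` and
#' optionally `sample_size`.  Multiple rows per (population, allele) --
#' multiple published sources -- are collapsed with [weighted_frequency()]
#' (unweighted mean if `sample_size` is absent).
#'
#' @param path TSV path.
#' @return An `hla_frequencies` object.
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("population", "allele", "frequency") %in% names(tab)))
  if (is.null(tab$sample_size)) tab$sample_size <- 1
  key <- paste(tab$population, tab$allele, sep = "\r")
  agg <- lapply(split(tab, key), function(d) {
    data.frame(population = d$population[1L], allele = d$allele[1L],
               frequency = weighted_frequency(d$frequency, d$sample_size),
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, agg)
  rownames(entries) <- NULL
  hla_frequencies(entries[order(entries$population, entries$allele), ])
}

#' Write an `hla_frequencies` table as TSV
#' @param freqs An `hla_frequencies` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freqs, path) {
  utils::write.table(freqs$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Look up allele frequencies with a rare-allele floor
#'
#' Alleles absent from the table receive the floor frequency so that rare or
#' newly described alleles are never assigned zero prior probability.
#'
#' @param freqs An `hla_frequencies` object.
#' @param population Population label present in the table.
#' @param alleles Character vector of 4-digit allele names.
#' @param floor Frequency substituted for missing alleles (default `1e-5`).
#' @return Numeric vector of frequencies.
#' @export
allele_frequency <- function(freqs, population, alleles, floor = 1e-5) {
  stopifnot(inherits(freqs, "hla_frequencies"))
  if (!population %in% freqs$populations) {
    stop("unknown population: ", population)
  }
  sub <- freqs$entries[freqs$entries$population == population, ]
  f <- sub$frequency[match(alleles, sub$allele)]
  f[is.na(f) | f < floor] <- floor
  f
}
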
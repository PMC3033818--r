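# End-to-end genotyping of a pooled read set.

#' Genotype every sample in a multiplexed read pool
#'
#' Runs the complete pipeline: demultiplex by barcode, assign reads to
#' locus/exon by primer, place reads with the plumbing aligner (or accept
#' pre-aligned reads via `aligned`), remove misaligned reads by SNP
#' homology, summarise coverage, and call the genotype at every locus of
#' every sample.
#'
#' @param reads data.frame `id`, `seq`, `qual` (e.g. [read_fastq()] or a
#'   simulated pool's `reads`).
#' @param barcodes A `barcode_manifest`.
#' @param primers A `primer_manifest`.
#' @param dict An `hla_dictionary`.
#' @param freqs An `hla_frequencies`, or `NULL`.
#' @param population Population label, or `NULL` for a uniform prior.
#' @param aligned Optional pre-aligned assigned-read data.frame (e.g. from
#'   [ingest_alignments()]); when given, `reads`/`barcodes`/`primers` may be
#'   `NULL` and the demux and alignment stages are skipped.
#' @param p_err Phase error rate (default 0.01).
#' @param qual_floor Minimum base quality (default 5).
#' @param homology_threshold Misalignment-filter threshold (default 0.75).
#' @param barcode_mismatch,primer_mismatch Matching tolerances (defaults 0
#'   and 1).
#' @param ... Further arguments passed to [call_locus()].
#' @return List of class `hla_pool_result`: `calls` (data.frame with one
#'   row per sample-locus: best pair, posterior, matching set size and
#'   members, depth, flags), `call_objects` (list of `hla_call`),
#'   `coverage`, and the `demux`, `locus_assignment` and `alignment`
#'   reports.
#' @export
hla_genotype_pool <- function(reads, barcodes, primers, dict, freqs = NULL,
                              population = NULL, aligned = NULL,
                              p_err = 0.01, qual_floor = 5L,
                              homology_threshold = 0.75,
                              barcode_mismatch = 0L, primer_mismatch = 1L,
                              ...) {
  demux_report <- NULL
  locus_report <- NULL
  align_report <- NULL
  if (is.null(aligned)) {
    dm <- demultiplex(reads, barcodes, max_mismatch = barcode_mismatch)
    demux_report <- dm$report
    la <- assign_locus(dm$assigned, primers, max_mismatch = primer_mismatch)
    locus_report <- la$report
    pa <- plumbing_align(la$assigned, dict)
    align_report <- list(aligned = nrow(pa$reads), unaligned = pa$unaligned)
    aligned <- pa$reads
  }
  mf <- misalignment_filter(aligned, dict, threshold = homology_threshold,
                            qual_floor = qual_floor)
  kept <- mf$reads
  samples <- if (!is.null(demux_report)) demux_report$samples else
    sort(unique(kept$sample))
  coverage <- depth_of_coverage(kept, dict, samples = samples)

  call_objects <- list()
  rows <- list()
  for (s in samples) {
    sreads <- kept[kept$sample == s, , drop = FALSE]
    for (locus in dictionary_loci(dict)) {
      cl <- call_locus(sreads, dict, locus, freqs = freqs,
                       population = population, p_err = p_err,
                       qual_floor = qual_floor, sample = s, ...)
      key <- paste(s, locus, sep = "|")
      call_objects[[key]] <- cl
      ms <- if (is.null(cl$matching_set)) "" else
        paste(paste(cl$matching_set$allele1, cl$matching_set$allele2,
                    sep = "/"), collapse = ";")
      rows[[key]] <- data.frame(
        sample = s, locus = locus, status = cl$status,
        allele1 = cl$best[1L], allele2 = cl$best[2L],
        posterior = cl$posterior,
        n_matching = if (is.null(cl$matching_set)) 0L else nrow(cl$matching_set),
        matching_set = ms,
        mean_depth = cl$mean_depth,
        flags = paste(cl$flags, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  calls <- do.call(rbind, rows)
  calls <- calls[order(calls$sample, calls$locus), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(calls = calls, call_objects = call_objects,
                 coverage = coverage, demux = demux_report,
                 locus_assignment = locus_report, alignment = align_report,
                 filter = list(removed = mf$removed, kept = nrow(kept))),
            class = "hla_pool_result")
}

#' @export
print.hla_pool_result <- function(x, ...) {
  ok <- sum(x$calls$status == "ok")
  cat(sprintf("HLA pool result: %d calls (%d ok, %d no-call)\n",
              nrow(x$calls), ok, nrow(x$calls) - ok))
  if (!is.null(x$demux)) {
    cat(sprintf("  demux parse rate: %.1f%%\n", 100 * x$demux$parse_rate))
  }
  invisible(x)
}

#' Write genotype calls as TSV
#'
#' Rows are ordered by sample then locus and numeric columns printed with
#' full precision, so identical inputs give byte-identical files.
#'
#' @param result An `hla_pool_result` (or its `calls` data.frame).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hla_calls <- function(result, path) {
  calls <- if (inherits(result, "hla_pool_result")) result$calls else result
  calls <- calls[order(calls$sample, calls$locus), , drop = FALSE]
  calls$posterior <- sprintf("%.10g", calls$posterior)
  calls$mean_depth <- sprintf("%.10g", calls$mean_depth)
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
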
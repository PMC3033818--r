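# FASTQ input/output.  Reads are carried internally as a plain data.frame
# with columns id, seq, qual (Sanger Phred+33 quality encoding).

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (Sanger quality encoding, uncompressed or gzip).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  data.frame(
    id = sub("\\s.*$", "", names(ss)),
    seq = as.character(ss),
    qual = as.character(S4Vectors::mcols(ss)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write a read table as FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
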
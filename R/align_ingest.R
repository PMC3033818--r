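# Producing per-locus aligned reads: either ingest external SAM/BAM
# alignments or place locus-assigned reads with the built-in plumbing
# aligner; then remove misaligned reads by SNP homology and summarise depth
# of coverage.
#
# An "assigned read" is a row of a data.frame with columns:
#   read_id, sample, locus, exon, start (1-based alignment column of the
#   first aligned base), seq (reference-oriented bases), qual, strand.

.EMPTY_ASSIGNED <- data.frame(
  read_id = character(0), sample = character(0), locus = character(0),
  exon = character(0), start = integer(0), seq = character(0),
  qual = character(0), strand = character(0), stringsAsFactors = FALSE
)

#' Ingest external SAM/BAM alignments into dictionary coordinates
#'
#' Reads alignments produced by any external aligner run against the
#' consensus references exported by [write_consensus_fasta()] (reference
#' names `<locus>|<exon>`).  Soft-clipped ends are removed, positions are
#' mapped into master-alignment column space through the dictionary's
#' reference-to-column map, and unmapped, secondary, supplementary and
#' indel-containing records are skipped and counted (the caller uses a
#' substitution-only model).
#'
#' The sample id is taken from the leading `<sample>:` field of the query
#' name when present (the simulator writes ids in that form), otherwise from
#' the `sample` argument.
#'
#' @param path SAM or BAM file.
#' @param dict An `hla_dictionary` whose consensus the reads were aligned to.
#' @param sample Fallback sample id.
#' @return List with `reads` (assigned-read data.frame) and `skipped`
#'   (named counts: `unmapped`, `secondary`, `indel`).
#' @export
ingest_alignments <- function(path, dict, sample = "sample") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, tmp, overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(c(path, tmp)), add = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual")
  )
  bam <- Rsamtools::scanBam(path, param = p)[[1L]]
  n <- length(bam$qname)
  skipped <- c(unmapped = 0L, secondary = 0L, indel = 0L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    flag <- bam$flag[i]
    if (bitwAnd(flag, 4L) != 0L) { skipped["unmapped"] <- skipped["unmapped"] + 1L; next }
    if (bitwAnd(flag, 256L) != 0L || bitwAnd(flag, 2048L) != 0L) {
      skipped["secondary"] <- skipped["secondary"] + 1L; next
    }
    cigar <- bam$cigar[i]
    ops <- .parse_cigar(cigar)
    if (any(ops$op %in% c("I", "D", "N"))) {
      skipped["indel"] <- skipped["indel"] + 1L; next
    }
    if (any(!ops$op %in% c("M", "S", "H", "=", "X"))) {
      stop("unsupported CIGAR operation in ", cigar)
    }
    rname <- as.character(bam$rname[i])
    parts <- strsplit(rname, "|", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || is.null(dict$loci[[parts[1L]]]) ||
        is.null(dict$loci[[parts[1L]]]$exons[[parts[2L]]])) {
      stop("alignment reference name not exported by the dictionary: ", rname)
    }
    locus <- parts[1L]; exon <- parts[2L]
    e <- dict$loci[[locus]]$exons[[exon]]
    seq <- as.character(bam$seq[i])
    qual <- as.character(bam$qual[i])
    # strip soft clips (hard clips consume no read bases)
    keep_ops <- ops[ops$op != "H", , drop = FALSE]
    first <- 1L
    if (nrow(keep_ops) > 0L && keep_ops$op[1L] == "S") {
      first <- keep_ops$len[1L] + 1L
      keep_ops <- keep_ops[-1L, , drop = FALSE]
    }
    last <- nchar(seq)
    if (nrow(keep_ops) > 0L && keep_ops$op[nrow(keep_ops)] == "S") {
      last <- last - keep_ops$len[nrow(keep_ops)]
      keep_ops <- keep_ops[-nrow(keep_ops), , drop = FALSE]
    }
    seq <- substr(seq, first, last)
    qual <- substr(qual, first, last)
    pos <- bam$pos[i]
    if (pos < 1L || pos + nchar(seq) - 1L > length(e$ref_to_col)) {
      stop("alignment at ", rname, ":", pos, " extends past the reference")
    }
    qname <- bam$qname[i]
    smp <- if (grepl(":", qname, fixed = TRUE)) {
      strsplit(qname, ":", fixed = TRUE)[[1L]][1L]
    } else sample
    rows[[i]] <- data.frame(
      read_id = qname, sample = smp, locus = locus, exon = exon,
      start = e$ref_to_col[pos], seq = toupper(seq), qual = qual,
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  reads <- if (length(rows) > 0L) do.call(rbind, rows) else .EMPTY_ASSIGNED
  list(reads = reads, skipped = skipped)
}

.parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1L]]
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

#' Place locus-assigned reads with the built-in plumbing aligner
#'
#' A deliberately minimal, gap-free local aligner used as internal plumbing:
#' each read is slid along the consensus of its assigned locus/exon and
#' scored +1 per match, -1 per mismatch at every offset; the best-scoring
#' offset wins (ties broken toward the smallest offset).  Reads longer than
#' the amplicon are truncated to its length; a read is reported unaligned if
#' its best score falls below `min_score_frac` times its (truncated) length.
#' Production-scale use should substitute any external aligner via
#' [ingest_alignments()].
#'
#' @param reads data.frame from [assign_locus()] (columns `id`, `sample`,
#'   `seq`, `qual`, `locus`, `exon`, `strand`; inserts reference-oriented).
#' @param dict An `hla_dictionary`.
#' @param min_score_frac Score acceptance threshold as a fraction of read
#'   length (default 0.75).
#' @return List with `reads` (assigned-read data.frame) and `unaligned`
#'   count.
#' @export
plumbing_align <- function(reads, dict, min_score_frac = 0.75) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) return(list(reads = .EMPTY_ASSIGNED, unaligned = 0L))
  if (is.null(reads$sample)) reads$sample <- "sample"
  out <- vector("list", nrow(reads))
  unaligned <- 0L
  key <- paste(reads$locus, reads$exon, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    locus <- reads$locus[idx[1L]]; exon <- reads$exon[idx[1L]]
    e <- .get_exon(.get_locus(dict, locus), locus, exon)
    cons <- e$consensus_codes
    L <- length(cons)
    for (i in idx) {
      r <- .encode(reads$seq[i])
      nlen <- length(r)
      if (nlen > L) { r <- r[seq_len(L)]; nlen <- L }
      if (nlen < 1L) { unaligned <- unaligned + 1L; next }
      n_off <- L - nlen + 1L
      best_score <- -Inf; best_off <- NA_integer_
      for (off in seq_len(n_off)) {
        matches <- sum(r == cons[off:(off + nlen - 1L)], na.rm = TRUE)
        score <- 2L * matches - nlen
        if (score > best_score) { best_score <- score; best_off <- off }
      }
      if (best_score < min_score_frac * nlen) { unaligned <- unaligned + 1L; next }
      out[[i]] <- data.frame(
        read_id = reads$id[i], sample = reads$sample[i], locus = locus,
        exon = exon, start = best_off,
        seq = substr(reads$seq[i], 1L, nlen),
        qual = substr(reads$qual[i], 1L, nlen),
        strand = reads$strand[i], stringsAsFactors = FALSE
      )
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  aligned <- if (length(out) > 0L) do.call(rbind, out) else .EMPTY_ASSIGNED
  rownames(aligned) <- NULL
  list(reads = aligned, unaligned = unaligned)
}

#' Remove misaligned reads by SNP homology
#'
#' For each read, over the polymorphic columns it covers (with known bases
#' of at least `qual_floor` quality), the filter computes the fraction of
#' columns agreeing with each dictionary allele and keeps the read if the
#' best such fraction -- its SNP homology with the closest matching allele --
#' is at least `threshold`.  Reads covering fewer than two usable
#' polymorphic columns cannot meaningfully fail the threshold and are kept.
#'
#' @param reads Assigned-read data.frame (alignment-space coordinates).
#' @param dict An `hla_dictionary`.
#' @param threshold Minimum SNP homology (default 0.75, attained counts as
#'   passing).
#' @param qual_floor Bases below this Phred quality are treated as unknown
#'   (default 5).
#' @return List with `reads` (kept rows) and `removed` count.
#' @export
misalignment_filter <- function(reads, dict, threshold = 0.75, qual_floor = 5L) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) return(list(reads = reads, removed = 0L))
  keep <- rep(TRUE, nrow(reads))
  key <- paste(reads$locus, reads$exon, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    locus <- reads$locus[idx[1L]]; exon <- reads$exon[idx[1L]]
    e <- .get_exon(.get_locus(dict, locus), locus, exon)
    poly <- e$polymorphic
    if (length(poly) < 1L) next
    amat_poly <- e$mat[, poly, drop = FALSE]
    for (i in idx) {
      start <- reads$start[i]
      end <- start + nchar(reads$seq[i]) - 1L
      cov <- which(poly >= start & poly <= end)
      if (length(cov) == 0L) next
      b <- .encode(reads$seq[i])[poly[cov] - start + 1L]
      q <- .qual_to_int(reads$qual[i])[poly[cov] - start + 1L]
      usable <- !is.na(b) & b <= 4L & q >= qual_floor
      if (sum(usable) < 2L) next
      cols <- cov[usable]
      obs <- b[usable]
      agree <- amat_poly[, cols, drop = FALSE] == matrix(obs, nrow(amat_poly),
                                                         length(obs), byrow = TRUE)
      homology <- max(rowMeans(agree))
      if (homology < threshold) keep[i] <- FALSE
    }
  }
  list(reads = reads[keep, , drop = FALSE], removed = sum(!keep))
}

#' Depth of coverage per sample, locus and exon
#'
#' @param reads Assigned-read data.frame (normally after
#'   [misalignment_filter()]).
#' @param dict An `hla_dictionary`.
#' @param samples,loci Optional vectors fixing which sample/locus/exon cells
#'   are summarised (so cells with zero reads appear as uncovered); defaults
#'   to those present in `reads` / the whole dictionary.
#' @return An object of class `hla_coverage`: list with `summary` (data.frame
#'   `sample`, `locus`, `exon`, `n_reads`, `mean_depth`, `uncovered`) and
#'   `depth` (named list of per-column depth vectors, keys
#'   `"sample|locus|exon"`).  `mean_depth` is the mean of the full per-column
#'   vector, uncovered columns included.
#' @export
depth_of_coverage <- function(reads, dict, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- sort(unique(reads$sample))
  if (is.null(loci)) loci <- dictionary_loci(dict)
  summary_rows <- list()
  depth <- list()
  for (s in samples) {
    for (locus in loci) {
      lc <- .get_locus(dict, locus)
      for (exon in names(lc$exons)) {
        L <- lc$exons[[exon]]$length
        sel <- reads$sample == s & reads$locus == locus & reads$exon == exon
        d <- integer(L)
        if (any(sel)) {
          starts <- reads$start[sel]
          ends <- starts + nchar(reads$seq[sel]) - 1L
          # difference-array accumulation
          delta <- integer(L + 1L)
          for (j in seq_along(starts)) {
            delta[starts[j]] <- delta[starts[j]] + 1L
            delta[ends[j] + 1L] <- delta[ends[j] + 1L] - 1L
          }
          d <- cumsum(delta[seq_len(L)])
        }
        key <- paste(s, locus, exon, sep = "|")
        depth[[key]] <- d
        summary_rows[[key]] <- data.frame(
          sample = s, locus = locus, exon = exon, n_reads = sum(sel),
          mean_depth = mean(d), uncovered = all(d == 0L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(sample = character(0), locus = character(0), exon = character(0),
               n_reads = integer(0), mean_depth = numeric(0), uncovered = logical(0))
  rownames(summary) <- NULL
  structure(list(summary = summary, depth = depth), class = "hla_coverage")
}

#' @export
print.hla_coverage <- function(x, ...) {
  cat(sprintf("Coverage over %d sample/locus/exon cells; mean depth %.1f\n",
              nrow(x$summary), mean(x$summary$mean_depth)))
  invisible(x)
}

#' Write a coverage summary as TSV
#' @param coverage An `hla_coverage` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  utils::write.table(coverage$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
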
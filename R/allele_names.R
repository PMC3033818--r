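#' Parse an HLA allele name
#'
#' Allele names follow current HLA nomenclature at 4-digit (protein-level)
#' resolution, rendered as `"LOCUS*GG:PP"` (for example `"A*02:07"`), or at
#' 2-digit (allele-group) resolution as `"LOCUS*GG"`.
#'
#' @param x Character vector of allele names.
#' @return A data.frame with columns `locus`, `group` and `protein`
#'   (`protein` is `NA` for 2-digit names).
#' @examples
#' parse_hla_allele(c("A*02:07", "C*02"))
#' @export
parse_hla_allele <- function(x) {
  stopifnot(is.character(x))
  m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9-]*)\\*([0-9]+)(?::([0-9]+[A-Z]?))?$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed allele name(s): ", paste(x[bad], collapse = ", "))
  }
  data.frame(
    locus = vapply(m, `[`, character(1), 2L),
    group = vapply(m, `[`, character(1), 3L),
    protein = {
      p <- vapply(m, `[`, character(1), 4L)
      p[p == ""] <- NA_character_
      p
    },
    stringsAsFactors = FALSE
  )
}

#' Render allele name fields back into nomenclature strings
#'
#' @param locus,group,protein Character vectors of equal length; `protein`
#'   may be `NA` for 2-digit group names.
#' @return Character vector of rendered names; `format_hla_allele` is the
#'   inverse of [parse_hla_allele()].
#' @export
format_hla_allele <- function(locus, group, protein = NA_character_) {
  n <- max(length(locus), length(group), length(protein))
  locus <- rep_len(locus, n)
  group <- rep_len(group, n)
  protein <- rep_len(protein, n)
  ifelse(is.na(protein),
    paste0(locus, "*", group),
    paste0(locus, "*", group, ":", protein)
  )
}

#' Truncate 4-digit allele names to 2-digit allele groups
#'
#' Drops the protein field, e.g. `"A*02:07"` becomes `"A*02"`.  Names already
#' at 2-digit resolution are returned unchanged.
#'
#' @param x Character vector of allele names.
#' @return Character vector of 2-digit group names.
#' @examples
#' truncate_to_2digit(c("A*02:07", "B*39:24"))
#' @export
truncate_to_2digit <- function(x) {
  p <- parse_hla_allele(x)
  format_hla_allele(p$locus, p$group)
}

#' @rdname parse_hla_allele
#' @export
allele_locus <- function(x) parse_hla_allele(x)$locus
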
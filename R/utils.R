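#' Strip a trailing version suffix from an accession
#'
#' `"NM_000059.3"` becomes `"NM_000059"`; accessions without a version pass
#' through unchanged.
#'
#' @param id Character vector of accessions.
#' @return Character vector of versionless accessions.
#' @export
strip_version <- function(id) sub("\\.[0-9]+$", "", id)

#' Complement nucleotide characters (vectorised, per string)
#' @noRd
comp_base <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

#' Reverse-complement one or more nucleotide strings
#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a single codon, stop written as "X"
#' @noRd
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (is.na(aa)) return("?")
  if (aa == "*") "X" else unname(aa)
}

#' Format an allele frequency for tabular output
#'
#' Frequencies in (0, 1e-3) are printed in scientific notation with two
#' decimals (`"1.00E-04"`); everything else in plain decimal notation.
#' Full numeric precision is kept internally; this only affects printing.
#'
#' @param x Numeric vector of frequencies.
#' @return Character vector.
#' @export
format_af <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (v > 0 && v < 1e-3) toupper(sprintf("%.2E", v))
    else format(v, scientific = FALSE, trim = TRUE, digits = 10)
  }, character(1), USE.NAMES = FALSE)
}

#' Apply a chromosome alias map
#'
#' Chromosome names are otherwise taken verbatim (no implicit "chr"
#' normalisation); an explicit alias map is applied before any lookup.
#'
#' @param chrom Character vector of chromosome names.
#' @param alias Named character vector, `names(alias)` are input names and
#'   values their replacements, or `NULL` for identity.
#' @return Character vector of (possibly renamed) chromosomes.
#' @export
apply_chrom_alias <- function(chrom, alias = NULL) {
  if (is.null(alias)) return(chrom)
  hit <- chrom %in% names(alias)
  chrom[hit] <- unname(alias[chrom[hit]])
  chrom
}

`%||%` <- function(a, b) if (is.null(a)) b else a
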
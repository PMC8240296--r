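# Projection between CDS, transcript and genomic coordinates. All three
# systems are 1-based; transcript coordinates run 5'->3' along the spliced
# mRNA, so on the minus strand transcript base 1 is the genomically
# rightmost base of the rank-1 exon. Exon lookup is a cumulative-width
# search; the naive per-base enumeration (`per_base_map`) serves as the
# exhaustive oracle in the test suite.

#' Map a CDS position to its transcript coordinate
#'
#' @param model A coding `tx_model`.
#' @param cds_pos 1-based position within the CDS.
#' @return Integer transcript coordinate `cds_tx_start + cds_pos - 1`.
#' @export
cds_to_transcript <- function(model, cds_pos) {
  if (!is_coding(model))
    stop("no-CDS error: transcript ", model$transcript_id, " is non-coding")
  cl <- cds_length(model)
  if (cds_pos < 1L || cds_pos > cl)
    stop("out-of-CDS error: position ", cds_pos, " outside CDS of length ",
         cl, " in transcript ", model$transcript_id)
  model$cds_tx_start + as.integer(cds_pos) - 1L
}

#' Project a transcript coordinate onto the genome
#'
#' Walks exons in transcript order accumulating widths; within the
#' containing exon the genomic position is `g_start + offset` on `+` and
#' `g_end - offset` on `-`. Exon boundaries belong to their exon (closed
#' intervals).
#'
#' @param model A `tx_model`.
#' @param tx_pos 1-based transcript coordinate.
#' @return One-row `data.frame` (a genomic locus) with columns `chrom`,
#'   `g_start`, `g_end`, `width`, `strand`, `exon_id`, `exon_rank`,
#'   `tx_start`, `tx_end`; for a single base `g_start == g_end` and
#'   `tx_start == tx_end == tx_pos`.
#' @export
transcript_to_genomic <- function(model, tx_pos) {
  len <- transcript_length(model)
  if (tx_pos < 1L || tx_pos > len)
    stop("out-of-transcript error: position ", tx_pos,
         " outside transcript ", model$transcript_id, " of length ", len)
  w <- model$exons$g_end - model$exons$g_start + 1L
  cum <- cumsum(w)
  idx <- findInterval(tx_pos - 0.5, c(0, cum)) # containing exon, transcript order
  prev <- if (idx > 1L) cum[idx - 1L] else 0L
  offset <- as.integer(tx_pos) - prev - 1L
  e <- model$exons[idx, ]
  g <- if (model$strand == "+") e$g_start + offset else e$g_end - offset
  data.frame(chrom = model$chrom, g_start = g, g_end = g, width = 1L,
             strand = model$strand, exon_id = e$exon_id, exon_rank = e$rank,
             tx_start = as.integer(tx_pos), tx_end = as.integer(tx_pos),
             stringsAsFactors = FALSE)
}

#' Map a genomic position back to a transcript coordinate
#'
#' Inverse of [transcript_to_genomic()] on exonic bases.
#'
#' @param model A `tx_model`.
#' @param chrom Chromosome of the queried position (must equal the
#'   model's chromosome).
#' @param g_pos 1-based genomic position.
#' @return Integer transcript coordinate.
#' @export
genomic_to_transcript <- function(model, chrom, g_pos) {
  if (chrom != model$chrom)
    stop("chromosome mismatch: transcript ", model$transcript_id, " is on ",
         model$chrom, ", queried ", chrom)
  ex <- model$exons
  hit <- which(g_pos >= ex$g_start & g_pos <= ex$g_end)
  if (!length(hit)) {
    d <- min(abs(g_pos - c(ex$g_start, ex$g_end)))
    stop("not-exonic error: ", chrom, ":", g_pos,
         " is intronic or outside transcript ", model$transcript_id,
         " (nearest exon boundary ", d, " bp away)")
  }
  w <- ex$g_end - ex$g_start + 1L
  cum <- cumsum(w)
  prev <- if (hit > 1L) cum[hit - 1L] else 0L
  offset <- if (model$strand == "+") g_pos - ex$g_start[hit] else
    ex$g_end[hit] - g_pos
  as.integer(prev + offset + 1L)
}

#' Naive per-base transcript-to-genome map
#'
#' Element `i` is the genomic position of transcript base `i`, built by
#' plain concatenation of each exon's base run (reversed per exon on the
#' minus strand). Deliberately simple; used as the independent oracle for
#' the projection functions.
#'
#' @param model A `tx_model`.
#' @return Integer vector of length `transcript_length(model)`.
#' @export
per_base_map <- function(model) {
  runs <- lapply(seq_len(nrow(model$exons)), function(i) {
    e <- model$exons[i, ]
    if (model$strand == "+") seq.int(e$g_start, e$g_end)
    else seq.int(e$g_end, e$g_start)
  })
  as.integer(unlist(runs))
}
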
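# Coding-consequence annotation: splice the CDS out of the genome, apply a
# CDS substitution, translate both codons under the standard genetic code
# (stop written as "X"), and classify the exonic function in ANNOVAR-style
# vocabulary. Region classification (exonic / UTR / splicing / intronic /
# intergenic) for genomic variants lives here too.

#' Spliced transcript sequence from the genome
#' @noRd
transcript_sequence <- function(model, genome) {
  if (!model$chrom %in% names(genome))
    stop("chromosome ", model$chrom, " absent from the genome sequence")
  chromseq <- genome[[model$chrom]]
  parts <- vapply(seq_len(nrow(model$exons)), function(i) {
    e <- model$exons[i, ]
    if (e$g_end > length(chromseq))
      stop("exon ", e$exon_id, " exceeds length of ", model$chrom)
    s <- as.character(Biostrings::subseq(chromseq, e$g_start, e$g_end))
    if (model$strand == "-") revcomp(s) else s
  }, character(1))
  toupper(paste(parts, collapse = ""))
}

#' Spliced CDS sequence of a coding model
#'
#' Concatenates exonic genome sequence in transcript order (reverse-
#' complementing on the minus strand) and slices the CDS span.
#'
#' @param model A coding `tx_model`.
#' @param genome A [Biostrings::DNAStringSet] as from [load_genome()].
#' @return Character scalar of length `cds_length(model)`.
#' @export
spliced_cds_sequence <- function(model, genome) {
  if (!is_coding(model))
    stop("no-CDS error: transcript ", model$transcript_id, " is non-coding")
  txseq <- transcript_sequence(model, genome)
  substr(txseq, model$cds_tx_start, model$cds_tx_end)
}

#' Annotate the coding consequence of a CDS substitution
#'
#' Codon index and frame follow directly from the CDS position:
#' `codon_number = ceiling(cds_pos / 3)` and
#' `pos_in_codon = (cds_pos - 1) %% 3 + 1`. The reference codon is taken
#' from the spliced CDS; when the genome base disagrees with the declared
#' reference allele the row is flagged (`ref_mismatch`), not dropped.
#' Input alleles are interpreted in transcript (coding-strand)
#' orientation; `g_ref`/`g_alt` give the genome-strand alleles
#' (complemented on minus-strand models).
#'
#' @param model A coding `tx_model`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param change List from [parse_change()] (`ref`, `cds_pos`, `alt`).
#' @return List with `codon_number`, `pos_in_codon`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `exonic_function`, `aachange`,
#'   `ref_mismatch`, `locus` (from [transcript_to_genomic()]), `g_ref`,
#'   `g_alt`.
#' @export
annotate_consequence <- function(model, genome, change) {
  p <- change$cds_pos
  tx <- cds_to_transcript(model, p)  # validates coding state and range
  cdsseq <- spliced_cds_sequence(model, genome)
  actual_ref <- substr(cdsseq, p, p)
  codon_number <- as.integer(ceiling(p / 3))
  pos_in_codon <- as.integer((p - 1L) %% 3L + 1L)
  c0 <- (codon_number - 1L) * 3L + 1L
  ref_codon <- substr(cdsseq, c0, c0 + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- change$alt
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  exonic_function <-
    if (ref_aa == "?" || alt_aa == "?") "unknown"
    else if (ref_aa == alt_aa) "synonymous SNV"
    else if (alt_aa == "X") "stopgain"
    else if (ref_aa == "X") "stoploss"
    else if (codon_number == 1L && ref_codon == "ATG") "startloss"
    else "nonsynonymous SNV"
  locus <- transcript_to_genomic(model, tx)
  flip <- model$strand == "-"
  gene <- if (is.na(model$gene_symbol)) "" else model$gene_symbol
  aachange <- sprintf("%s:%s:exon%d:c.%s%d%s:p.%s%d%s",
                      gene, model$transcript_id, locus$exon_rank,
                      change$ref, p, change$alt,
                      ref_aa, codon_number, alt_aa)
  list(codon_number = codon_number, pos_in_codon = pos_in_codon,
       ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa,
       exonic_function = exonic_function, aachange = aachange,
       ref_mismatch = !identical(actual_ref, change$ref),
       locus = locus,
       g_ref = if (flip) comp_base(change$ref) else change$ref,
       g_alt = if (flip) comp_base(change$alt) else change$alt)
}

#' Build an interval index over a model set for region classification
#'
#' @param models Named list of `tx_model` objects.
#' @return A `region_index` list of [GenomicRanges::GRanges] (transcript
#'   spans, exons, CDS spans) keyed back to their models.
#' @export
build_region_index <- function(models) {
  if (!length(models)) {
    empty <- GenomicRanges::GRanges()
    return(structure(list(spans = empty, exons = empty, cds = empty,
                          models = models), class = "region_index"))
  }
  span_df <- do.call(rbind, lapply(models, function(m) {
    data.frame(chrom = m$chrom, start = min(m$exons$g_start),
               end = max(m$exons$g_end), tx = m$transcript_id,
               gene = m$gene_symbol, stringsAsFactors = FALSE)
  }))
  spans <- GenomicRanges::GRanges(span_df$chrom,
                                  IRanges::IRanges(span_df$start, span_df$end),
                                  tx = span_df$tx, gene = span_df$gene)
  exon_df <- do.call(rbind, lapply(models, function(m) {
    data.frame(chrom = m$chrom, start = m$exons$g_start,
               end = m$exons$g_end, tx = m$transcript_id,
               stringsAsFactors = FALSE)
  }))
  exons <- GenomicRanges::GRanges(exon_df$chrom,
                                  IRanges::IRanges(exon_df$start, exon_df$end),
                                  tx = exon_df$tx)
  cds_df <- do.call(rbind, lapply(models, function(m) {
    if (!is_coding(m)) return(NULL)
    sp <- cds_genomic_spans(m)
    data.frame(chrom = m$chrom, start = sp$g_start, end = sp$g_end,
               tx = m$transcript_id, stringsAsFactors = FALSE)
  }))
  cds <- if (is.null(cds_df)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(cds_df$chrom,
                           IRanges::IRanges(cds_df$start, cds_df$end),
                           tx = cds_df$tx)
  structure(list(spans = spans, exons = exons, cds = cds, models = models),
            class = "region_index")
}

#' Classify the genomic region of a variant
#'
#' Per overlapping transcript: `exonic` when the position lies on a CDS
#' base; `UTR5`/`UTR3` when exonic in a coding transcript but outside its
#' CDS; `splicing` when intronic within 2 bp of an exon boundary;
#' `intronic` elsewhere inside the transcript span; `intergenic` when no
#' transcript overlaps. Classes from multiple transcripts are combined by
#' the priority exonic > UTR5 > UTR3 > splicing > intronic.
#'
#' @param index A `region_index` from [build_region_index()] (a plain
#'   model list is accepted and indexed on the fly).
#' @param variant One-row `data.frame` or list with `chrom`, `g_start`.
#' @return List with `region` (character scalar) and `genes` (character
#'   vector of HGNC symbols of all overlapping transcripts).
#' @export
classify_region <- function(index, variant) {
  if (!inherits(index, "region_index")) index <- build_region_index(index)
  pos <- as.integer(variant$g_start)
  q <- GenomicRanges::GRanges(variant$chrom, IRanges::IRanges(pos, pos))
  sp_hits <- GenomicRanges::findOverlaps(q, index$spans)
  tx_hit <- S4Vectors::mcols(index$spans)$tx[S4Vectors::subjectHits(sp_hits)]
  genes <- unique(S4Vectors::mcols(index$spans)$gene[S4Vectors::subjectHits(sp_hits)])
  genes <- genes[!is.na(genes)]
  if (!length(tx_hit)) return(list(region = "intergenic", genes = character(0)))
  classes <- vapply(tx_hit, function(tid) {
    m <- index$models[[tid]]
    ex <- m$exons
    in_exon <- any(pos >= ex$g_start & pos <= ex$g_end)
    if (in_exon) {
      if (!is_coding(m)) return("intronic") # ncRNA exon: no finer class available
      txp <- genomic_to_transcript(m, variant$chrom, pos)
      if (txp >= m$cds_tx_start && txp <= m$cds_tx_end) return("exonic")
      # tx coordinates are already strand-aware, so < CDS start means 5'
      return(if (txp < m$cds_tx_start) "UTR5" else "UTR3")
    }
    near <- min(abs(pos - c(ex$g_start, ex$g_end)))
    if (near <= 2L) "splicing" else "intronic"
  }, character(1))
  prio <- c(exonic = 1, UTR5 = 2, UTR3 = 3, splicing = 4, intronic = 5)
  list(region = names(sort(prio[unique(classes)]))[1L], genes = genes)
}
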
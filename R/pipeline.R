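# The two user-facing commands. `convert_transcript_id()` turns
# transcript-relative changes into genomic variant rows (conversion-table
# schema); `pop_freq()` annotates genomic variants with per-population
# allele frequencies plus region / gene / exonic-function / amino-acid-
# change columns. Both are row-fault-tolerant: a bad input row yields a
# diagnostic row, never an abort.

CONVERSION_COLUMNS <- c("Transcript_version", "Nucleotide_changes",
                        "CDS_start_loc", "Ref", "Alt", "Chr",
                        "ensembl_transcript_id", "hgnc_symbol", "start",
                        "end", "width", "strand", "exon_id", "exon_rank",
                        "tx_start", "tx_end", "refsnp_id")

#' Load an annotation bundle
#'
#' A bundle directory replaces the original tool's online databases: a
#' transcript-model GTF, an ID crossref TSV, and optionally a genome
#' FASTA, a dbSNP-style VCF and one or more frequency panels. Paths come
#' from a `bundle.ini` key=value file in the directory when present
#' (keys: `gtf`, `fasta`, `crossref`, `dbsnp`, `species`,
#' `default_panel`, `panel.<name>.path`, `panel.<name>.format`,
#' `panel.<name>.subpops` comma-separated); otherwise the conventional
#' file names `transcripts.gtf`, `genome.fa`, `crossref.tsv`,
#' `dbsnp.vcf`, `panel_<name>.tsv` are probed.
#'
#' @param dir Bundle directory.
#' @return An `annotation_bundle` object.
#' @export
load_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("bundle directory not found: ", dir)
  ini <- file.path(dir, "bundle.ini")
  cfg <- list()
  if (file.exists(ini)) {
    for (ln in readLines(ini, warn = FALSE)) {
      ln <- trimws(ln)
      if (!nzchar(ln) || startsWith(ln, "#")) next
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0) stop("bundle.ini parse error: '", ln, "'")
      cfg[[trimws(substr(ln, 1, eq - 1))]] <- trimws(substr(ln, eq + 1, nchar(ln)))
    }
  }
  pth <- function(key, default) {
    rel <- cfg[[key]] %||% default
    if (is.null(rel)) return(NULL)
    p <- file.path(dir, rel)
    if (file.exists(p)) p else NULL
  }
  gtf <- pth("gtf", "transcripts.gtf")
  if (is.null(gtf)) stop("bundle load error: no transcript GTF in ", dir)
  crossref_path <- pth("crossref", "crossref.tsv")
  fasta <- pth("fasta", "genome.fa")
  dbsnp <- pth("dbsnp", "dbsnp.vcf")
  panel_keys <- grep("^panel\\.[^.]+\\.path$", names(cfg), value = TRUE)
  panel_names <- sub("^panel\\.([^.]+)\\.path$", "\\1", panel_keys)
  if (!length(panel_names)) {
    hits <- list.files(dir, pattern = "^panel_.*\\.tsv$")
    panel_names <- sub("^panel_(.*)\\.tsv$", "\\1", hits)
  }
  panels <- list()
  for (pn in panel_names) {
    ppath <- pth(paste0("panel.", pn, ".path"), paste0("panel_", pn, ".tsv"))
    fmt <- cfg[[paste0("panel.", pn, ".format")]] %||% "tsv"
    sp <- cfg[[paste0("panel.", pn, ".subpops")]]
    if (!is.null(sp)) sp <- trimws(strsplit(sp, ",")[[1L]])
    panels[[pn]] <- frequency_panel(pn, path = ppath, subpops = sp, format = fmt)
  }
  models <- load_transcript_models(gtf)
  b <- structure(list(
    dir = dir,
    species = cfg[["species"]] %||% "hsapiens",
    models = models,
    crossref = if (!is.null(crossref_path)) load_crossref(crossref_path) else NULL,
    genome = if (!is.null(fasta)) load_genome(fasta) else NULL,
    snp_db = if (!is.null(dbsnp)) load_snp_vcf(dbsnp) else NULL,
    panels = panels,
    default_panel = cfg[["default_panel"]] %||% "db_gnomAD_exome_freq",
    index = NULL
  ), class = "annotation_bundle")
  b$index <- build_region_index(models)
  b
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf("<annotation_bundle> %s: %d transcript model(s), %s genome, %s dbSNP, panels: %s\n",
              x$dir, length(x$models),
              if (is.null(x$genome)) "no" else "with",
              if (is.null(x$snp_db)) "no" else "with",
              if (length(x$panels)) paste(names(x$panels), collapse = ", ") else "none"))
  invisible(x)
}

#' Convert transcript-relative changes to genomic variant rows
#'
#' Per input row: resolve the transcript ID, map the CDS position to a
#' transcript coordinate and then onto the genome, and look up the rsID.
#' `Ref`/`Alt` are the coding-strand alleles as given; `genome_ref` /
#' `genome_alt` are the plus-strand alleles (complemented for
#' minus-strand transcripts) and are what position-based databases see.
#' Rows that fail (unknown ID, out-of-CDS position, non-coding model,
#' unparseable token) are emitted with their diagnostic in `note` and
#' empty data columns; the run never aborts on a row.
#'
#' @param user_table Path to the input CSV or a `data.frame` from
#'   [read_transcript_table()].
#' @param bundle An `annotation_bundle`.
#' @return `data.frame` in input order: the conversion-table columns
#'   (`Transcript_version`, `Nucleotide_changes`, `CDS_start_loc`, `Ref`,
#'   `Alt`, `Chr`, `ensembl_transcript_id`, `hgnc_symbol`, `start`,
#'   `end`, `width`, `strand`, `exon_id`, `exon_rank`, `tx_start`,
#'   `tx_end`, `refsnp_id`) followed by `genome_ref`, `genome_alt`,
#'   `note`.
#' @export
convert_transcript_id <- function(user_table, bundle) {
  if (is.character(user_table)) user_table <- read_transcript_table(user_table)
  n <- nrow(user_table)
  out <- data.frame(
    Transcript_version = user_table$transcript_id,
    Nucleotide_changes = user_table$token,
    CDS_start_loc = NA_integer_, Ref = NA_character_, Alt = NA_character_,
    Chr = NA_character_, ensembl_transcript_id = NA_character_,
    hgnc_symbol = NA_character_, start = NA_integer_, end = NA_integer_,
    width = NA_integer_, strand = NA_character_, exon_id = NA_character_,
    exon_rank = NA_integer_, tx_start = NA_integer_, tx_end = NA_integer_,
    refsnp_id = NA_character_, genome_ref = NA_character_,
    genome_alt = NA_character_, note = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (!is.na(user_table$error[i])) { out$note[i] <- user_table$error[i]; next }
    res <- tryCatch({
      model <- suppressMessages(
        resolve_transcript(user_table$transcript_id[i], bundle$crossref,
                           bundle$models))
      change <- list(ref = user_table$ref[i], cds_pos = user_table$cds_pos[i],
                     alt = user_table$alt[i])
      tx <- cds_to_transcript(model, change$cds_pos)
      locus <- transcript_to_genomic(model, tx)
      flip <- model$strand == "-"
      g_ref <- if (flip) comp_base(change$ref) else change$ref
      g_alt <- if (flip) comp_base(change$alt) else change$alt
      rsid <- ""
      if (!is.null(bundle$snp_db))
        rsid <- lookup_rsid(bundle$snp_db,
                            list(chrom = locus$chrom, g_start = locus$g_start,
                                 ref = g_ref, alt = g_alt))
      list(model = model, change = change, locus = locus,
           g_ref = g_ref, g_alt = g_alt, rsid = rsid)
    }, error = function(e) e)
    if (inherits(res, "error")) { out$note[i] <- conditionMessage(res); next }
    out$CDS_start_loc[i] <- res$change$cds_pos
    out$Ref[i] <- res$change$ref; out$Alt[i] <- res$change$alt
    out$Chr[i] <- res$locus$chrom
    out$ensembl_transcript_id[i] <- res$model$transcript_id
    out$hgnc_symbol[i] <- res$model$gene_symbol
    out$start[i] <- res$locus$g_start; out$end[i] <- res$locus$g_end
    out$width[i] <- res$locus$width; out$strand[i] <- res$locus$strand
    out$exon_id[i] <- res$locus$exon_id; out$exon_rank[i] <- res$locus$exon_rank
    out$tx_start[i] <- res$locus$tx_start; out$tx_end[i] <- res$locus$tx_end
    out$refsnp_id[i] <- res$rsid
    out$genome_ref[i] <- res$g_ref; out$genome_alt[i] <- res$g_alt
  }
  out
}

SEVERITY <- c("stopgain" = 1, "stoploss" = 2, "startloss" = 3,
              "nonsynonymous SNV" = 4, "synonymous SNV" = 5, "unknown" = 6)

#' Annotate genomic variants with population frequencies and gene context
#'
#' Accepts any 1-based genomic variant table (it need not come from
#' [convert_transcript_id()]). Each variant is joined against the chosen
#' frequency panel (absent variants get `(Ref_freq, Alt_freq) = (1, 0)`
#' per subpopulation), classified by region, and — when it lands on a CDS
#' base — annotated per overlapping coding isoform with the amino-acid
#' change. Isoform labels use the crossref's UCSC accession when one
#' exists. When isoforms disagree, the most severe exonic-function class
#' is reported (stopgain > stoploss > startloss > nonsynonymous >
#' synonymous).
#'
#' @param variant_table Path to a CSV/BED file or a `data.frame` from
#'   [read_variant_table()].
#' @param panel_name Name of a panel configured in the bundle (default:
#'   the bundle's `default_panel`).
#' @param bundle An `annotation_bundle` with a genome loaded.
#' @param format,bed_dialect Passed to [read_variant_table()] when
#'   `variant_table` is a path.
#' @return `data.frame`: `Chr`, `Start`, `End`, `Ref`, `Alt`, the panel's
#'   `Ref_freq`/`Alt_freq` column pairs, then `Func.knownGene`,
#'   `Gene.knownGene`, `ExonicFunc.knownGene`, `AAChange.knownGene`.
#' @export
pop_freq <- function(variant_table, panel_name = NULL, bundle,
                     format = "csv", bed_dialect = "table1") {
  if (is.character(variant_table))
    variant_table <- read_variant_table(variant_table, format = format,
                                        bed_dialect = bed_dialect)
  panel_name <- panel_name %||% bundle$default_panel
  if (!panel_name %in% names(bundle$panels))
    stop("configuration error: panel '", panel_name,
         "' not configured in bundle; available: ",
         paste(names(bundle$panels), collapse = ", "))
  panel <- bundle$panels[[panel_name]]
  freq <- annotate_frequencies(variant_table, panel)
  n <- nrow(variant_table)
  func <- gene <- exonic <- aachange <- character(n)
  for (i in seq_len(n)) {
    v <- variant_table[i, ]
    cls <- classify_region(bundle$index, v)
    func[i] <- cls$region
    gene[i] <- paste(cls$genes, collapse = ";")
    if (cls$region != "exonic" || is.null(bundle$genome)) next
    entries <- character(0); sev <- character(0)
    for (m in bundle$models) {
      if (!is_coding(m) || m$chrom != v$chrom) next
      txp <- tryCatch(genomic_to_transcript(m, v$chrom, v$g_start),
                      error = function(e) NULL)
      if (is.null(txp) || txp < m$cds_tx_start || txp > m$cds_tx_end) next
      cds_pos <- txp - m$cds_tx_start + 1L
      flip <- m$strand == "-"
      change <- list(ref = if (flip) comp_base(v$ref) else v$ref,
                     cds_pos = cds_pos,
                     alt = if (flip) comp_base(v$alt) else v$alt)
      cons <- tryCatch(annotate_consequence(m, bundle$genome, change),
                       error = function(e) NULL)
      if (is.null(cons)) next
      label <- isoform_label(bundle$crossref, m$transcript_id)
      aas <- sub(sprintf(":%s:", m$transcript_id), sprintf(":%s:", label),
                 cons$aachange, fixed = TRUE)
      entries <- c(entries, aas)
      sev <- c(sev, cons$exonic_function)
    }
    if (length(entries)) {
      aachange[i] <- paste(entries, collapse = ",")
      exonic[i] <- sev[which.min(SEVERITY[sev])]
    }
  }
  freq$Func.knownGene <- func
  freq$Gene.knownGene <- gene
  freq$ExonicFunc.knownGene <- exonic
  freq$AAChange.knownGene <- aachange
  names(freq)[match(c("chrom", "g_start", "g_end", "ref", "alt"), names(freq))] <-
    c("Chr", "Start", "End", "Ref", "Alt")
  freq
}

#' Preferred display accession for an isoform
#' @noRd
isoform_label <- function(crossref, transcript_id) {
  if (is.null(crossref)) return(transcript_id)
  df <- crossref$table
  hit <- which(strip_version(df$ensembl_transcript_id) ==
                 strip_version(transcript_id) & nzchar(df$ucsc_id))
  if (length(hit)) df$ucsc_id[hit[1L]] else transcript_id
}

#' Write a result table as CSV with panel-style frequency formatting
#'
#' Frequency columns (`*_Ref_freq` / `*_Alt_freq`) are printed via
#' [format_af()] (scientific notation below 1e-3, as in the panel
#' outputs); all other columns are written as-is.
#'
#' @param df Result `data.frame`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_result_csv <- function(df, path) {
  out <- df
  fc <- grep("_(Ref|Alt)_freq$", names(out))
  for (j in fc) out[[j]] <- format_af(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
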
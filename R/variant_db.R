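# rsID lookup from a dbSNP-style VCF and multi-population allele-frequency
# annotation from local panel files (wide TSV or VCF with per-population AF
# INFO keys). The absent-variant convention is (Ref_freq, Alt_freq) = (1, 0)
# per subpopulation: "not seen in the panel" is reported as a monomorphic
# reference site, which users should not over-interpret biologically.

BUILTIN_PANELS <- list(
  db_gnomAD_exome_freq  = c("ALL", "AFR", "AMR", "ASJ", "EAS", "FIN", "NFE", "SAS", "OTH"),
  db_gnomAD_genome_freq = c("ALL", "AFR", "AMR", "ASJ", "EAS", "FIN", "NFE", "SAS", "OTH"),
  db_1000Genomes_5pop_freq = c("EAS", "AMR", "AFR", "EUR", "SAS"),
  db_TWB_GWG_freq = "ALL",
  db_TWB_NGS_freq = "ALL"
)

# getFIX() drops to a bare vector for single-record files; keep a matrix
vcf_fix_frame <- function(v) {
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  as.data.frame(fix, stringsAsFactors = FALSE)
}

#' Load a dbSNP-style VCF for rsID lookup
#'
#' The file must be position-sorted within each chromosome; an unsorted
#' file is rejected at load (index error).
#'
#' @param path VCF 4.x file path.
#' @return A `snp_db` object.
#' @export
load_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_frame(v)
  df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   id = fix$ID, ref = toupper(fix$REF),
                   alt = toupper(fix$ALT), stringsAsFactors = FALSE)
  unsorted <- tapply(df$pos, df$chrom, is.unsorted)
  if (any(unlist(unsorted)))
    stop("index error: VCF ", path, " is not position-sorted (chromosome ",
         names(unsorted)[which(unlist(unsorted))[1L]], ")")
  structure(list(table = df), class = "snp_db")
}

#' Look up the rsID of a genomic variant
#'
#' A match requires chromosome and position equality, reference-allele
#' equality, and membership of the alternate allele in the record's ALT
#' list (so multi-allelic records match any of their alternates).
#'
#' @param snp_db A `snp_db` from [load_snp_vcf()].
#' @param variant One-row `data.frame`/list with `chrom`, `g_start`,
#'   `ref`, `alt`.
#' @return The ID field of the matching record, or `""` when absent.
#' @export
lookup_rsid <- function(snp_db, variant) {
  df <- snp_db$table
  i <- which(df$chrom == variant$chrom & df$pos == variant$g_start &
               df$ref == variant$ref)
  for (k in i) {
    if (variant$alt %in% strsplit(df$alt[k], ",", fixed = TRUE)[[1L]])
      return(df$id[k])
  }
  ""
}

#' Define a frequency panel
#'
#' Built-in panel names carry their subpopulation sets (gnomAD exome and
#' genome: ALL, AFR, AMR, ASJ, EAS, FIN, NFE, SAS, OTH; 1000 Genomes:
#' EAS, AMR, AFR, EUR, SAS; the two Taiwan Biobank panels: ALL).
#' User-defined panels must supply `subpops` explicitly.
#'
#' @param panel_name Panel identifier (column-name prefix in the output).
#' @param path Path to the frequency table (wide TSV or VCF).
#' @param subpops Ordered character vector of subpopulation codes;
#'   defaults to the built-in set for known names.
#' @param format `"tsv"` (columns `Chr`, `Pos`, `Ref`, `Alt`,
#'   `AF_<POP>`...) or `"vcf"` (per-population AF INFO keys).
#' @param info_keys Named character vector mapping subpop code to VCF
#'   INFO key; default `AF` for `ALL` and `AF_<pop lowercased>` otherwise.
#' @return A `freq_panel` object (records loaded eagerly).
#' @export
frequency_panel <- function(panel_name, path = NULL, subpops = NULL,
                            format = c("tsv", "vcf"), info_keys = NULL) {
  format <- match.arg(format)
  if (is.null(subpops)) {
    if (!panel_name %in% names(BUILTIN_PANELS))
      stop("configuration error: unknown panel '", panel_name,
           "'; known panels: ", paste(names(BUILTIN_PANELS), collapse = ", "))
    subpops <- BUILTIN_PANELS[[panel_name]]
  }
  if (!length(subpops) || anyDuplicated(subpops))
    stop("panel subpopulation codes must be non-empty and unique")
  records <- NULL
  if (!is.null(path)) {
    records <- if (format == "tsv") read_panel_tsv(path, subpops)
    else read_panel_vcf(path, subpops, info_keys)
    bad <- unlist(records[paste0("af_", subpops)])
    bad <- bad[!is.na(bad)]
    if (length(bad) && (any(bad < 0) || any(bad > 1)))
      stop("panel ", panel_name, ": allele frequencies outside [0, 1]")
  }
  structure(list(panel_name = panel_name, subpops = subpops,
                 source_path = path, records = records),
            class = "freq_panel")
}

read_panel_tsv <- function(path, subpops) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("Chr", "Pos", "Ref", "Alt")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("panel schema error: missing column(s) ", paste(miss, collapse = ", "))
  out <- data.frame(chrom = as.character(df$Chr), pos = as.integer(df$Pos),
                    ref = toupper(df$Ref), alt = toupper(df$Alt),
                    stringsAsFactors = FALSE)
  for (p in subpops) {
    col <- paste0("AF_", p)
    out[[paste0("af_", p)]] <- if (col %in% names(df)) as.numeric(df[[col]])
    else NA_real_
  }
  out
}

read_panel_vcf <- function(path, subpops, info_keys = NULL) {
  if (is.null(info_keys)) {
    info_keys <- ifelse(subpops == "ALL", "AF", paste0("AF_", tolower(subpops)))
    names(info_keys) <- subpops
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_frame(v)
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = toupper(fix$REF), alt = toupper(fix$ALT),
                    stringsAsFactors = FALSE)
  for (p in subpops) {
    out[[paste0("af_", p)]] <-
      suppressWarnings(as.numeric(vcfR::extract.info(v, element = info_keys[[p]])))
  }
  out
}

#' Annotate variants with per-subpopulation allele frequencies
#'
#' For each variant and subpopulation, a matching panel record yields
#' `Ref_freq = 1 - alt_freq` and `Alt_freq = alt_freq`; a variant absent
#' from the panel (or a subpopulation with no stored value) yields
#' `(1, 0)`. Output columns are named
#' `{panel}_{POP}_Ref_freq` / `{panel}_{POP}_Alt_freq` in panel order.
#' The function is total: one output row per input variant.
#'
#' @param variants `data.frame` with `chrom`, `g_start`, `ref`, `alt`
#'   (as from [read_variant_table()]).
#' @param panel A `freq_panel` with records loaded.
#' @return `data.frame`: the input columns followed by the frequency
#'   columns (numeric, full precision).
#' @export
annotate_frequencies <- function(variants, panel) {
  stopifnot(inherits(panel, "freq_panel"))
  if (is.null(panel$records))
    stop("panel '", panel$panel_name, "' has no frequency table loaded")
  rec <- panel$records
  out <- variants
  n <- nrow(variants)
  for (p in panel$subpops) {
    af <- rep(0, n)
    key <- paste0("af_", p)
    for (i in seq_len(n)) {
      j <- which(rec$chrom == variants$chrom[i] & rec$pos == variants$g_start[i] &
                   rec$ref == variants$ref[i] & rec$alt == variants$alt[i])
      if (length(j) && !is.na(rec[[key]][j[1L]])) af[i] <- rec[[key]][j[1L]]
    }
    out[[sprintf("%s_%s_Ref_freq", panel$panel_name, p)]] <- 1 - af
    out[[sprintf("%s_%s_Alt_freq", panel$panel_name, p)]] <- af
  }
  out
}

#' Minor-allele-frequency summary of annotated rows
#'
#' @param annotated Output of [annotate_frequencies()].
#' @param panel The `freq_panel` used to produce it.
#' @return Tidy long `data.frame` with columns `variant` (chrom:pos
#'   ref>alt label), `subpop`, `maf` where
#'   `maf = min(Ref_freq, Alt_freq)`.
#' @export
maf_summary <- function(annotated, panel) {
  lab <- sprintf("%s:%d %s>%s", annotated$chrom, annotated$g_start,
                 annotated$ref, annotated$alt)
  out <- do.call(rbind, lapply(panel$subpops, function(p) {
    rf <- annotated[[sprintf("%s_%s_Ref_freq", panel$panel_name, p)]]
    af <- annotated[[sprintf("%s_%s_Alt_freq", panel$panel_name, p)]]
    data.frame(variant = lab, subpop = p, maf = pmin(rf, af),
               stringsAsFactors = FALSE)
  }))
  out[order(out$variant), , drop = FALSE]
}

#' Bar plot of MAFs across subpopulations
#'
#' One panel per variant; requires ggplot2.
#'
#' @param maf_table Output of [maf_summary()].
#' @return A ggplot object.
#' @export
plot_maf <- function(maf_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plot_maf()")
  subpop <- maf <- NULL # satisfy static checks; columns of maf_table
  ggplot2::ggplot(maf_table, ggplot2::aes(x = subpop, y = maf)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~variant, scales = "free_y") +
    ggplot2::labs(x = "Subpopulation", y = "Minor allele frequency")
}
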
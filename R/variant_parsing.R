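# Parsing of nucleotide-change tokens ("A947G", "c.947A>G") and of the two
# user-facing input table shapes: the transcript CSV (Transcript_version,
# Nucleotide_changes) and genomic variant tables (CSV with
# Chr,Start,End,Ref,Alt header, or BED).

#' Parse a single-nucleotide change token
#'
#' Accepts the compact dialect `A947G` (ref, CDS position, alt) and the
#' HGVS-like dialect `947A>G`, each with an optional `c.` prefix.
#' Insertions, deletions and multi-base changes are rejected: only
#' width-1 substitutions are supported.
#'
#' @param token Character scalar.
#' @return List with elements `ref`, `cds_pos`, `alt`.
#' @export
parse_change <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  t <- sub("^c\\.", "", token)
  if (grepl("^[ACGT][0-9]+[ACGT]$", t)) {
    ref <- substr(t, 1L, 1L)
    alt <- substr(t, nchar(t), nchar(t))
    pos <- as.integer(substr(t, 2L, nchar(t) - 1L))
  } else if (grepl("^[0-9]+[ACGT]>[ACGT]$", t)) {
    pos <- as.integer(sub("^([0-9]+).*$", "\\1", t))
    ref <- sub("^[0-9]+([ACGT])>.*$", "\\1", t)
    alt <- sub("^.*>([ACGT])$", "\\1", t)
  } else {
    stop("parse error: cannot interpret nucleotide change token '", token, "'")
  }
  if (ref == alt)
    stop("degenerate-change error: ref equals alt in '", token, "'")
  if (pos < 1L)
    stop("parse error: CDS position must be >= 1 in '", token, "'")
  list(ref = ref, cds_pos = pos, alt = alt)
}

#' Format a parsed change in the compact dialect
#' @param change List as returned by [parse_change()].
#' @return Character scalar such as `"A947G"`.
#' @export
format_change <- function(change) {
  sprintf("%s%d%s", change$ref, change$cds_pos, change$alt)
}

#' Read a transcript-change table (CSV)
#'
#' Expects a header with `Transcript_version` and `Nucleotide_changes`
#' columns, one record per row. Token parse failures are collected per
#' row (with their row number) rather than aborting the read.
#'
#' @param path CSV file path or connection.
#' @return `data.frame` in input order with columns `row`,
#'   `transcript_id`, `token`, `ref`, `cds_pos`, `alt`, `error`
#'   (`NA` for clean rows).
#' @export
read_transcript_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  req <- c("Transcript_version", "Nucleotide_changes")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("schema error: transcript table must have header columns ",
         paste(req, collapse = ", "), "; missing ",
         paste(miss, collapse = ", "))
  n <- nrow(df)
  out <- data.frame(row = seq_len(n),
                    transcript_id = as.character(df$Transcript_version),
                    token = as.character(df$Nucleotide_changes),
                    ref = rep(NA_character_, n), cds_pos = rep(NA_integer_, n),
                    alt = rep(NA_character_, n),
                    error = rep(NA_character_, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ch <- tryCatch(parse_change(out$token[i]), error = function(e) e)
    if (inherits(ch, "error")) {
      out$error[i] <- sprintf("row %d: %s", i, conditionMessage(ch))
    } else {
      out$ref[i] <- ch$ref; out$cds_pos[i] <- ch$cds_pos; out$alt[i] <- ch$alt
    }
  }
  out
}

#' Read a genomic variant table (CSV or BED)
#'
#' All outputs are normalised to 1-based inclusive coordinates. The CSV
#' shape requires a `Chr,Start,End,Ref,Alt` header and is already 1-based
#' with `Start == End` for SNVs. For BED, two dialects exist:
#' `"standard0"` treats Start as 0-based half-open (Start is incremented);
#' `"table1"` (the default) takes coordinates as already 1-based with
#' `Start == End` for SNVs, the convention of this package's CSV shape.
#'
#' @param path File path or connection.
#' @param format `"csv"` or `"bed"`.
#' @param bed_dialect `"table1"` or `"standard0"`.
#' @param bed_columns Column order of the BED file; default
#'   `c("chrom","start","end","ref","alt")`.
#' @param chrom_alias Optional named character vector renaming
#'   chromosomes (see [apply_chrom_alias()]).
#' @return `data.frame` with columns `chrom`, `g_start`, `g_end`, `ref`,
#'   `alt`.
#' @export
read_variant_table <- function(path, format = c("csv", "bed"),
                               bed_dialect = c("table1", "standard0"),
                               bed_columns = c("chrom", "start", "end", "ref", "alt"),
                               chrom_alias = NULL) {
  format <- match.arg(format)
  bed_dialect <- match.arg(bed_dialect)
  if (format == "csv") {
    # colClasses: a bare "T" allele must never become logical TRUE
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    req <- c("Chr", "Start", "End", "Ref", "Alt")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("schema error: variant CSV must have header Chr,Start,End,Ref,Alt; missing ",
           paste(miss, collapse = ", "))
    out <- data.frame(chrom = as.character(df$Chr),
                      g_start = as.integer(gsub(",", "", df$Start)),
                      g_end = as.integer(gsub(",", "", df$End)),
                      ref = toupper(as.character(df$Ref)),
                      alt = toupper(as.character(df$Alt)),
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE, colClasses = "character")
    if (ncol(df) < length(bed_columns))
      stop("BED parse error: expected at least ", length(bed_columns),
           " tab-separated columns")
    names(df)[seq_along(bed_columns)] <- bed_columns
    start <- as.integer(df$start)
    if (bed_dialect == "standard0") start <- start + 1L
    out <- data.frame(chrom = as.character(df$chrom),
                      g_start = start, g_end = as.integer(df$end),
                      ref = toupper(as.character(df$ref)),
                      alt = toupper(as.character(df$alt)),
                      stringsAsFactors = FALSE)
  }
  bad <- which(out$g_start > out$g_end)
  if (length(bad))
    stop("coordinate error: Start > End at record ", bad[1L])
  ok <- grepl("^[ACGT]$", out$ref) & grepl("^[ACGT]$", out$alt)
  if (any(!ok))
    stop("allele error: non-ACGT ref/alt at record ", which(!ok)[1L])
  out$chrom <- apply_chrom_alias(out$chrom, chrom_alias)
  out
}
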
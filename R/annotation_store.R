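# Transcript models, genome sequence and ID cross-references, loaded from
# local files. A model is the substrate for all coordinate projection:
# chromosome, strand, exons in transcript (5'->3') order, and the CDS span
# in transcript coordinates.

#' Construct a transcript model
#'
#' @param transcript_id Versioned or versionless accession (Ensembl, RefSeq
#'   or UCSC namespace).
#' @param gene_symbol HGNC symbol (or `NA`).
#' @param chrom Chromosome name, taken verbatim.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `exon_id`, `g_start`, `g_end`,
#'   `rank`; coordinates are 1-based inclusive; `rank` is 1-based in
#'   transcript (5'->3') order, so on the minus strand rank 1 is the
#'   genomically rightmost exon.
#' @param cds_tx_start,cds_tx_end 1-based transcript coordinates of the
#'   first and last CDS base, or `NA` for a non-coding model.
#' @param cds_incomplete Logical; `TRUE` when the CDS length is not a
#'   multiple of 3 (model kept, flagged).
#' @return An object of class `tx_model`.
#' @export
new_tx_model <- function(transcript_id, gene_symbol, chrom, strand, exons,
                         cds_tx_start = NA_integer_, cds_tx_end = NA_integer_,
                         cds_incomplete = FALSE) {
  stopifnot(is.data.frame(exons),
            all(c("exon_id", "g_start", "g_end", "rank") %in% names(exons)))
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  exons <- exons[order(exons$rank), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$g_start > exons$g_end))
    stop("exon with g_start > g_end in transcript ", transcript_id)
  gs <- exons$g_start[order(exons$g_start)]
  ge <- exons$g_end[order(exons$g_start)]
  if (nrow(exons) > 1L && any(gs[-1L] <= ge[-nrow(exons)]))
    stop("overlapping exons in transcript ", transcript_id)
  expected <- if (strand == "+") order(exons$g_start) else order(-exons$g_start)
  if (!identical(expected, seq_len(nrow(exons))))
    stop("exon ranks of transcript ", transcript_id,
         " do not follow transcript order for strand ", strand)
  m <- structure(list(
    transcript_id = transcript_id,
    gene_symbol   = gene_symbol,
    chrom         = chrom,
    strand        = strand,
    exons         = exons,
    cds_tx_start  = as.integer(cds_tx_start),
    cds_tx_end    = as.integer(cds_tx_end),
    cds_incomplete = isTRUE(cds_incomplete)
  ), class = "tx_model")
  len <- transcript_length(m)
  if (is_coding(m)) {
    if (m$cds_tx_start < 1L || m$cds_tx_end < m$cds_tx_start ||
        m$cds_tx_end > len)
      stop("CDS span [", m$cds_tx_start, ",", m$cds_tx_end,
           "] outside transcript ", transcript_id, " of length ", len)
  }
  m
}

#' Total spliced length of a transcript model
#' @param model A `tx_model`.
#' @return Integer number of transcript bases (sum of exon widths).
#' @export
transcript_length <- function(model) {
  sum(model$exons$g_end - model$exons$g_start + 1L)
}

#' CDS length of a coding model
#' @param model A `tx_model`.
#' @return Integer CDS length, or `NA` for non-coding models.
#' @export
cds_length <- function(model) {
  if (!is_coding(model)) return(NA_integer_)
  model$cds_tx_end - model$cds_tx_start + 1L
}

#' Is a model protein-coding?
#' @param model A `tx_model`.
#' @return Logical.
#' @export
is_coding <- function(model) {
  !is.na(model$cds_tx_start) && !is.na(model$cds_tx_end)
}

#' @export
print.tx_model <- function(x, ...) {
  cat(sprintf("<tx_model> %s (%s) %s:%s, %d exon(s), length %d",
              x$transcript_id, x$gene_symbol %||% NA, x$chrom, x$strand,
              nrow(x$exons), transcript_length(x)))
  if (is_coding(x))
    cat(sprintf(", CDS tx %d-%d (%d nt%s)\n", x$cds_tx_start, x$cds_tx_end,
                cds_length(x), if (x$cds_incomplete) ", incomplete" else ""))
  else cat(", non-coding\n")
  invisible(x)
}

#' Load transcript models from a GTF file
#'
#' Builds one [new_tx_model()] per `transcript_id` from `exon` and `CDS`
#' features. Exons are sorted into transcript order (ascending genomic
#' start on `+`, descending on `-`); ranks come from the `exon_number`
#' attribute when present and are recomputed otherwise. Transcripts
#' without CDS features are retained as non-coding. A CDS whose length is
#' not a multiple of 3 flags the model as `cds_incomplete`.
#'
#' @param path Path to a GTF2.2 file whose exon/CDS records carry
#'   `transcript_id` (and ideally `gene_name`, `exon_number`, `exon_id`)
#'   attributes.
#' @return Named list of `tx_model` objects (names = transcript IDs).
#' @export
load_transcript_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (!length(body)) return(structure(list(), names = character(0)))
  if (length(body)) {
    ntab <- vapply(gregexpr("\t", lines[body], fixed = TRUE),
                   function(g) if (g[1L] == -1L) 0L else length(g), integer(1))
    bad <- which(ntab != 8L)
    if (length(bad))
      stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, found %d",
                   body[bad[1L]], ntab[bad[1L]] + 1L))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  mc <- S4Vectors::mcols(gr)
  ex <- gr[mc$type == "exon"]
  cds <- gr[mc$type == "CDS"]
  models <- list()
  for (tid in unique(S4Vectors::mcols(ex)$transcript_id)) {
    e <- ex[S4Vectors::mcols(ex)$transcript_id == tid]
    emc <- S4Vectors::mcols(e)
    strand <- as.character(BiocGenerics::strand(e))[1L]
    chrom <- as.character(GenomicRanges::seqnames(e))[1L]
    gene <- NA_character_
    if (!is.null(emc$gene_name) && !is.na(emc$gene_name[1L])) {
      gene <- emc$gene_name[1L]
    } else if (!is.null(emc$gene_id)) gene <- emc$gene_id[1L]
    ord <- if (strand == "+") order(BiocGenerics::start(e)) else
      order(-BiocGenerics::start(e))
    rank <- if (!is.null(emc$exon_number) && !anyNA(emc$exon_number)) {
      as.integer(as.character(emc$exon_number))
    } else {
      r <- integer(length(e)); r[ord] <- seq_along(e); r
    }
    exon_id <- if (!is.null(emc$exon_id) && !anyNA(emc$exon_id)) {
      as.character(emc$exon_id)
    } else sprintf("%s.E%d", tid, rank)
    exons <- data.frame(exon_id = exon_id,
                        g_start = BiocGenerics::start(e),
                        g_end = BiocGenerics::end(e),
                        rank = rank, stringsAsFactors = FALSE)
    model <- new_tx_model(tid, gene, chrom, strand, exons)
    cd <- cds[S4Vectors::mcols(cds)$transcript_id == tid]
    if (length(cd)) {
      cs <- BiocGenerics::start(cd); ce <- BiocGenerics::end(cd)
      for (k in seq_along(cd)) {
        inside <- any(exons$g_start <= cs[k] & ce[k] <= exons$g_end)
        if (!inside)
          stop("model-consistency error: CDS segment ", chrom, ":", cs[k],
               "-", ce[k], " lies outside every exon of transcript ", tid)
      }
      first_g <- if (strand == "+") min(cs) else max(ce)
      last_g  <- if (strand == "+") max(ce) else min(cs)
      cds_tx_start <- genomic_to_transcript(model, chrom, first_g)
      cds_tx_end   <- genomic_to_transcript(model, chrom, last_g)
      clen <- cds_tx_end - cds_tx_start + 1L
      model <- new_tx_model(tid, gene, chrom, strand, exons,
                            cds_tx_start, cds_tx_end,
                            cds_incomplete = (clen %% 3L != 0L))
    }
    models[[tid]] <- model
  }
  models
}

#' Load transcript models from a refFlat (genePred-style) file
#'
#' Reads the 11-column UCSC refFlat layout (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) with
#' its native 0-based half-open coordinates, converting to the package's
#' 1-based inclusive convention. `cdsStart == cdsEnd` marks a non-coding
#' entry.
#'
#' @param path Path to a tab-separated refFlat file without header.
#' @return Named list of `tx_model` objects.
#' @export
load_refflat <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 11L)
    stop("refFlat parse error: expected 11 columns, found ", ncol(df))
  models <- list()
  for (i in seq_len(nrow(df))) {
    tid <- df[i, 2L]; strand <- df[i, 4L]
    starts <- as.integer(strsplit(df[i, 10L], ",")[[1L]]) + 1L
    ends <- as.integer(strsplit(df[i, 11L], ",")[[1L]])
    n <- length(starts)
    ord <- if (strand == "+") order(starts) else order(-starts)
    exons <- data.frame(exon_id = sprintf("%s.E%d", tid, seq_len(n)),
                        g_start = starts[ord], g_end = ends[ord],
                        rank = seq_len(n), stringsAsFactors = FALSE)
    model <- new_tx_model(tid, df[i, 1L], df[i, 3L], strand, exons)
    cds_g_start <- as.integer(df[i, 7L]) + 1L
    cds_g_end <- as.integer(df[i, 8L])
    if (cds_g_end >= cds_g_start) {
      first_g <- if (strand == "+") cds_g_start else cds_g_end
      last_g  <- if (strand == "+") cds_g_end else cds_g_start
      a <- genomic_to_transcript(model, df[i, 3L], first_g)
      b <- genomic_to_transcript(model, df[i, 3L], last_g)
      model <- new_tx_model(tid, df[i, 1L], df[i, 3L], strand, exons, a, b,
                            cds_incomplete = ((b - a + 1L) %% 3L != 0L))
    }
    models[[tid]] <- model
  }
  models
}

#' Serialise transcript models back to GTF
#'
#' Writes `exon` and `CDS` features with `transcript_id`, `gene_name`,
#' `exon_number` and `exon_id` attributes, such that
#' [load_transcript_models()] reconstructs the models field-by-field.
#'
#' @param models Named list of `tx_model` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_models_gtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    gene <- if (is.na(m$gene_symbol)) m$transcript_id else m$gene_symbol
    for (i in seq_len(nrow(m$exons))) {
      e <- m$exons[i, ]
      attrs <- sprintf('transcript_id "%s"; gene_name "%s"; exon_number "%d"; exon_id "%s";',
                       m$transcript_id, gene, e$rank, e$exon_id)
      lines <- c(lines, paste(m$chrom, "txvar", "exon", e$g_start, e$g_end,
                              ".", m$strand, ".", attrs, sep = "\t"))
    }
    if (is_coding(m)) {
      spans <- cds_genomic_spans(m)
      for (i in seq_len(nrow(spans))) {
        attrs <- sprintf('transcript_id "%s"; gene_name "%s";',
                         m$transcript_id, gene)
        lines <- c(lines, paste(m$chrom, "txvar", "CDS", spans$g_start[i],
                                spans$g_end[i], ".", m$strand, "0", attrs,
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Genomic intervals covered by a model's CDS, one row per exon touched
#' @noRd
cds_genomic_spans <- function(model) {
  stopifnot(is_coding(model))
  w <- model$exons$g_end - model$exons$g_start + 1L
  cum <- cumsum(w)
  prev <- c(0L, cum[-length(cum)])
  out <- NULL
  for (i in seq_len(nrow(model$exons))) {
    a <- max(model$cds_tx_start, prev[i] + 1L)
    b <- min(model$cds_tx_end, cum[i])
    if (a > b) next
    g1 <- transcript_to_genomic(model, a)$g_start
    g2 <- transcript_to_genomic(model, b)$g_start
    out <- rbind(out, data.frame(g_start = min(g1, g2), g_end = max(g1, g2)))
  }
  out[order(out$g_start), , drop = FALSE]
}

#' Load an ID cross-reference table
#'
#' @param path TSV with a header naming at least `refseq_id`, `ucsc_id`,
#'   `ensembl_transcript_id`, `hgnc_symbol`; an optional `canonical_flag`
#'   column (logical-ish) marks preferred isoforms; any further columns are
#'   carried through untouched.
#' @return A `crossref_map` object.
#' @export
load_crossref <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("refseq_id", "ucsc_id", "ensembl_transcript_id", "hgnc_symbol")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("crossref schema error: missing required column(s) ",
         paste(miss, collapse = ", "),
         "; expected header with ", paste(req, collapse = ", "))
  if (!"canonical_flag" %in% names(df)) df$canonical_flag <- FALSE
  df$canonical_flag <- tolower(as.character(df$canonical_flag)) %in%
    c("true", "t", "1", "yes")
  # a fully-versioned key must map to a single Ensembl transcript
  for (col in c("refseq_id", "ucsc_id")) {
    keys <- df[[col]]
    versioned <- !is.na(keys) & nzchar(keys) & grepl("\\.[0-9]+$", keys)
    tab <- tapply(df$ensembl_transcript_id[versioned], keys[versioned],
                  function(x) length(unique(x)))
    dup <- names(tab)[tab > 1L]
    if (length(dup))
      stop("crossref load error: versioned key(s) with conflicting targets: ",
           paste(dup, collapse = ", "))
  }
  structure(list(table = df), class = "crossref_map")
}

#' Look up crossref rows for an accession
#'
#' Exact (versioned) matches are preferred; when none exist, both the
#' stored keys and the query are compared versionless.
#'
#' @param xref A `crossref_map`.
#' @param query_id Accession in any of the three namespaces.
#' @return The matching rows of the crossref table (possibly 0 rows).
#' @export
crossref_lookup <- function(xref, query_id) {
  df <- xref$table
  cols <- c("refseq_id", "ucsc_id", "ensembl_transcript_id")
  exact <- Reduce(`|`, lapply(cols, function(cl) !is.na(df[[cl]]) & df[[cl]] == query_id))
  if (any(exact)) return(df[exact, , drop = FALSE])
  q <- strip_version(query_id)
  loose <- Reduce(`|`, lapply(cols, function(cl) {
    k <- df[[cl]]
    !is.na(k) & strip_version(k) == q
  }))
  df[loose, , drop = FALSE]
}

#' Resolve a user-supplied transcript ID to one loaded model
#'
#' Ensembl IDs already present in the model set are returned directly,
#' bypassing the crossref. Otherwise the crossref supplies candidate
#' Ensembl transcripts; a RefSeq ID mapping to several Ensembl transcripts
#' is disambiguated deterministically: rows with `canonical_flag` first,
#' then the lexicographically smallest `ensembl_transcript_id`. The chosen
#' mapping is reported via [message()].
#'
#' @param query_id RefSeq, UCSC or Ensembl accession, optionally versioned.
#' @param crossref A `crossref_map` (may be `NULL` for Ensembl-only input).
#' @param models Named list of `tx_model` objects.
#' @return The resolved `tx_model`.
#' @export
resolve_transcript <- function(query_id, crossref, models) {
  keys <- names(models)
  if (query_id %in% keys) return(models[[query_id]])
  hit <- which(strip_version(keys) == strip_version(query_id))
  if (length(hit) == 1L) return(models[[hit]])
  if (length(hit) > 1L) return(models[[hit[order(keys[hit])][1L]]])
  if (is.null(crossref))
    stop("unresolved transcript ID '", query_id, "': not in the model set and no crossref loaded")
  rows <- crossref_lookup(crossref, query_id)
  if (nrow(rows) == 0L)
    stop("unresolved transcript ID '", query_id, "': no crossref row matches")
  cand <- unique(rows$ensembl_transcript_id)
  canon <- vapply(cand, function(e)
    any(rows$canonical_flag[rows$ensembl_transcript_id == e]), logical(1))
  cand <- cand[order(!canon, cand)]
  chosen <- cand[1L]
  idx <- which(keys == chosen)
  if (!length(idx)) idx <- which(strip_version(keys) == strip_version(chosen))
  if (!length(idx))
    stop("missing-model error: crossref maps '", query_id, "' to ", chosen,
         " which is absent from the loaded bundle")
  message("resolved ", query_id, " -> ", keys[idx[1L]])
  models[[idx[1L]]]
}

#' Load a genome FASTA
#'
#' Sequence names are truncated at the first whitespace and sequences
#' uppercased, giving the chromosome -> sequence mapping used by the
#' consequence module.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
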
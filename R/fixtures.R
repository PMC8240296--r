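# Seeded synthetic annotation-bundle generator. Produces a genome FASTA,
# transcript GTF, crossref TSV, dbSNP-style VCF, a gnomAD-exome-style
# frequency panel, ready-made pipeline input CSVs, and gold-standard
# expected outputs. The gold tables are computed by deliberately naive
# code (string concatenation, linear scans, full-protein diffs) kept in
# this file and never called by the production modules, so they act as an
# independent oracle. Regeneration with the same spec is byte-identical.
# Structural variety (strands, exon counts, UTR lengths), not biological
# realism, is the goal.

#' Specification for a synthetic annotation bundle
#'
#' @param seed Integer RNG seed; the same spec regenerates byte-identical
#'   files.
#' @param n_transcripts Number of transcript models (each on its own
#'   synthetic chromosome).
#' @param exon_count_range,exon_width_range,intron_width_range Integer
#'   ranges (min, max) sampled per transcript/exon/intron.
#' @param utr5_range,utr3_range 5'/3' UTR length ranges in bases.
#' @param minus_strand_fraction Fraction of transcripts placed on the
#'   minus strand.
#' @param n_panel_variants Number of planted variants (at least 5 of
#'   which are CAA->TAA stopgains).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 42L, n_transcripts = 100L,
                         exon_count_range = c(1L, 6L),
                         exon_width_range = c(30L, 200L),
                         intron_width_range = c(20L, 200L),
                         utr5_range = c(5L, 60L), utr3_range = c(5L, 60L),
                         minus_strand_fraction = 0.5,
                         n_panel_variants = 30L) {
  spec <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
               exon_count_range = as.integer(exon_count_range),
               exon_width_range = as.integer(exon_width_range),
               intron_width_range = as.integer(intron_width_range),
               utr5_range = as.integer(utr5_range),
               utr3_range = as.integer(utr3_range),
               minus_strand_fraction = minus_strand_fraction,
               n_panel_variants = as.integer(n_panel_variants))
  for (f in c("exon_count_range", "exon_width_range", "intron_width_range",
              "utr5_range", "utr3_range")) {
    r <- spec[[f]]
    if (length(r) != 2L || any(r < 1L) || r[1L] > r[2L])
      stop("generation error: ", f, " must be a positive (min, max) pair")
  }
  if (spec$minus_strand_fraction < 0 || spec$minus_strand_fraction > 1)
    stop("generation error: minus_strand_fraction must be in [0, 1]")
  if (spec$n_transcripts < 0L || spec$n_panel_variants < 0L)
    stop("generation error: counts must be non-negative")
  if (spec$n_transcripts > 0L && spec$n_panel_variants > 0L &&
      spec$n_panel_variants < min(5L, spec$n_transcripts))
    stop("generation error: n_panel_variants too small for stopgain planting")
  structure(spec, class = "fixture_spec")
}

# --- deliberately naive helpers (oracle side; base R only) ------------------

naive_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

naive_translate <- function(cds) {
  n <- nchar(cds) %/% 3L
  vapply(seq_len(n), function(k)
    unname(Biostrings::GENETIC_CODE[substr(cds, 3L * k - 2L, 3L * k)]),
    character(1))
}

# classify a substitution by rebuilding and diffing the full protein
naive_classify <- function(cds, cds_pos, alt) {
  mut <- cds
  substr(mut, cds_pos, cds_pos) <- alt
  p0 <- naive_translate(cds); p1 <- naive_translate(mut)
  d <- which(p0 != p1)
  codon <- as.integer(ceiling(cds_pos / 3))
  if (!length(d))
    return(list(codon = codon, ref_aa = sub("\\*", "X", p0[codon]),
                alt_aa = sub("\\*", "X", p0[codon]), class = "synonymous SNV"))
  d <- d[1L]
  aa0 <- p0[d]; aa1 <- p1[d]
  cls <- if (aa1 == "*") "stopgain"
  else if (aa0 == "*") "stoploss"
  else if (d == 1L) "startloss"
  else "nonsynonymous SNV"
  list(codon = d, ref_aa = sub("\\*", "X", aa0), alt_aa = sub("\\*", "X", aa1),
       class = cls)
}

rand_codons <- function(n) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")), 1L,
                              paste, collapse = ""), stops)
  sample(all_codons, n, replace = TRUE)
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- generator --------------------------------------------------------------

#' Generate a complete synthetic annotation bundle
#'
#' Writes `genome.fa`, `transcripts.gtf`, `crossref.tsv`, `dbsnp.vcf`,
#' `panel_db_gnomAD_exome_freq.tsv`, `bundle.ini`, the two pipeline input
#' CSVs (`transcript_changes.csv`, `variants.csv`) and the gold tables
#' `gold_per_base_map.csv`, `gold_conversion.csv`, `gold_consequence.csv`
#' into `out_dir`. Every planted CDS starts with ATG, ends with a stop,
#' contains no internal stop codon and has length divisible by 3; at
#' least 5 planted variants are CAA->TAA stopgains. All gold values come
#' from the naive oracle code in this file, never from the production
#' modules.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Writable output directory (created if needed).
#' @return Invisibly, a list with `dir`, the per-transcript `truth`
#'   records and the planted `variants` table.
#' @export
generate_bundle <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  rint <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

  truth <- list()
  fasta <- character(0)
  gtf <- character(0)
  xref <- data.frame(refseq_id = character(0), ucsc_id = character(0),
                     ensembl_transcript_id = character(0),
                     hgnc_symbol = character(0),
                     canonical_flag = character(0), stringsAsFactors = FALSE)
  pbm_rows <- list()
  for (i in seq_len(spec$n_transcripts)) {
    strand <- if (stats::runif(1) < spec$minus_strand_fraction) "-" else "+"
    n_ex <- rint(spec$exon_count_range)
    widths <- vapply(seq_len(n_ex), function(k) rint(spec$exon_width_range),
                     integer(1))
    introns <- if (n_ex > 1L)
      vapply(seq_len(n_ex - 1L), function(k) rint(spec$intron_width_range),
             integer(1)) else integer(0)
    utr5 <- rint(spec$utr5_range); utr3 <- rint(spec$utr3_range)
    cds_len <- sum(widths) - utr5 - utr3
    if (cds_len < 12L) { widths[n_ex] <- widths[n_ex] + (12L - cds_len); cds_len <- 12L }
    rem <- cds_len %% 3L
    utr3 <- utr3 + rem; cds_len <- cds_len - rem
    n_codons <- cds_len %/% 3L
    codons <- rand_codons(n_codons - 2L)
    caa_codon <- if (n_codons > 3L) sample(2:(n_codons - 1L), 1L) else 2L
    codons[caa_codon - 1L] <- "CAA"
    cds <- paste0("ATG", paste(codons, collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    tx_seq <- paste0(rand_bases(utr5), cds, rand_bases(utr3))
    total <- sum(widths)
    span <- total + sum(introns)
    chrom <- sprintf("chrS%03d", i)
    # exon genomic intervals in transcript (rank) order
    g_start <- g_end <- integer(n_ex)
    if (strand == "+") {
      cur <- 101L
      for (k in seq_len(n_ex)) {
        g_start[k] <- cur; g_end[k] <- cur + widths[k] - 1L
        cur <- g_end[k] + (if (k < n_ex) introns[k] else 0L) + 1L
      }
    } else {
      cur <- 100L + span
      for (k in seq_len(n_ex)) {
        g_end[k] <- cur; g_start[k] <- cur - widths[k] + 1L
        cur <- g_start[k] - (if (k < n_ex) introns[k] else 0L) - 1L
      }
    }
    # plant exon chunks into a background genome
    glen <- 100L + span + 100L
    gchar <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    cum <- cumsum(widths); prev <- c(0L, cum[-n_ex])
    for (k in seq_len(n_ex)) {
      chunk <- substr(tx_seq, prev[k] + 1L, cum[k])
      if (strand == "-") chunk <- naive_revcomp(chunk)
      gchar[g_start[k]:g_end[k]] <- strsplit(chunk, "")[[1L]]
    }
    # naive per-base map (placement bookkeeping, not the production mapper)
    pbm <- unlist(lapply(seq_len(n_ex), function(k) {
      if (strand == "+") g_start[k]:g_end[k] else g_end[k]:g_start[k]
    }))
    tid <- sprintf("ENSTF%011d", i)
    gene <- sprintf("GENEF%03d", i)
    exon_ids <- sprintf("ENSEF%011d", i * 1000L + seq_len(n_ex))
    for (k in seq_len(n_ex)) {
      gtf <- c(gtf, paste(chrom, "txvarfix", "exon", g_start[k], g_end[k], ".",
                          strand, ".",
                          sprintf('transcript_id "%s"; gene_name "%s"; exon_number "%d"; exon_id "%s";',
                                  tid, gene, k, exon_ids[k]), sep = "\t"))
    }
    # CDS genomic segments by naive per-base scan over tx coords
    cds_tx <- (utr5 + 1L):(utr5 + cds_len)
    cds_g <- sort(pbm[cds_tx])
    brk <- c(0L, which(diff(cds_g) != 1L), length(cds_g))
    for (b in seq_len(length(brk) - 1L)) {
      seg <- cds_g[(brk[b] + 1L):brk[b + 1L]]
      gtf <- c(gtf, paste(chrom, "txvarfix", "CDS", seg[1L], seg[length(seg)],
                          ".", strand, "0",
                          sprintf('transcript_id "%s"; gene_name "%s";', tid, gene),
                          sep = "\t"))
    }
    fasta <- c(fasta, paste0(">", chrom), paste(gchar, collapse = ""))
    xref <- rbind(xref, data.frame(
      refseq_id = sprintf("NMF_%06d", i), ucsc_id = sprintf("ucfix%03d.1", i),
      ensembl_transcript_id = tid, hgnc_symbol = gene,
      canonical_flag = "true", stringsAsFactors = FALSE))
    pbm_rows[[i]] <- data.frame(transcript_id = tid, tx_pos = seq_along(pbm),
                                g_pos = pbm, stringsAsFactors = FALSE)
    truth[[tid]] <- list(i = i, tid = tid, gene = gene, chrom = chrom,
                         strand = strand, widths = widths, g_start = g_start,
                         g_end = g_end, exon_ids = exon_ids, utr5 = utr5,
                         utr3 = utr3, cds = cds, cds_len = cds_len,
                         caa_codon = caa_codon, pbm = pbm,
                         refseq = sprintf("NMF_%06d", i))
  }
  # an ambiguous RefSeq key exercising the canonical/lexicographic tie-break
  if (spec$n_transcripts >= 2L) {
    xref <- rbind(xref,
      data.frame(refseq_id = "NMF_SHARED", ucsc_id = "",
                 ensembl_transcript_id = truth[[1L]]$tid, hgnc_symbol = truth[[1L]]$gene,
                 canonical_flag = "false", stringsAsFactors = FALSE),
      data.frame(refseq_id = "NMF_SHARED", ucsc_id = "",
                 ensembl_transcript_id = truth[[2L]]$tid, hgnc_symbol = truth[[2L]]$gene,
                 canonical_flag = "true", stringsAsFactors = FALSE))
  }

  # --- planted variants and their gold annotations --------------------------
  nv <- spec$n_panel_variants
  variants <- NULL
  if (nv > 0L && spec$n_transcripts > 0L) {
    n_stop <- min(5L, spec$n_transcripts, nv)
    pick_tx <- c(seq_len(n_stop),
                 sample(seq_len(spec$n_transcripts), max(0L, nv - n_stop),
                        replace = TRUE))
    seen <- character(0)
    rows <- list()
    for (j in seq_along(pick_tx)) {
      tr <- truth[[pick_tx[j]]]
      if (j <= n_stop) {
        cds_pos <- (tr$caa_codon - 1L) * 3L + 1L
        ref <- "C"; alt <- "T"   # CAA -> TAA
      } else {
        repeat {
          cds_pos <- sample(4:tr$cds_len, 1L)
          if (!paste(tr$tid, cds_pos) %in% seen) break
        }
        ref <- substr(tr$cds, cds_pos, cds_pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      }
      seen <- c(seen, paste(tr$tid, cds_pos))
      tx_pos <- tr$utr5 + cds_pos
      g <- tr$pbm[tx_pos]
      rk <- which(cumsum(tr$widths) >= tx_pos)[1L]   # linear scan
      flip <- tr$strand == "-"
      g_ref <- if (flip) chartr("ACGT", "TGCA", ref) else ref
      g_alt <- if (flip) chartr("ACGT", "TGCA", alt) else alt
      cls <- naive_classify(tr$cds, cds_pos, alt)
      rows[[j]] <- data.frame(
        j = j, tid = tr$tid, refseq = tr$refseq, gene = tr$gene,
        chrom = tr$chrom, cds_pos = cds_pos, ref = ref, alt = alt,
        tx_pos = tx_pos, g_pos = g, exon_rank = rk,
        exon_id = tr$exon_ids[rk], strand = tr$strand,
        g_ref = g_ref, g_alt = g_alt, rsid = sprintf("rsF%04d", j),
        codon = cls$codon, ref_aa = cls$ref_aa, alt_aa = cls$alt_aa,
        class = cls$class, stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, rows)
  }

  # panel: ~60% of planted variants carry frequencies, some cells missing
  subpops <- BUILTIN_PANELS$db_gnomAD_exome_freq
  panel <- NULL
  if (!is.null(variants)) {
    in_panel <- stats::runif(nrow(variants)) < 0.6
    pv <- variants[in_panel, , drop = FALSE]
    if (nrow(pv)) {
      panel <- data.frame(Chr = pv$chrom, Pos = pv$g_pos, Ref = pv$g_ref,
                          Alt = pv$g_alt, stringsAsFactors = FALSE)
      for (p in subpops) {
        af <- round(stats::runif(nrow(pv)) * 0.5, 6L)
        af[stats::runif(nrow(pv)) < 0.2] <- NA
        panel[[paste0("AF_", p)]] <- af
      }
    }
    variants$in_panel <- in_panel
  }

  # --- all content built; write files ---------------------------------------
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(fasta, file.path(out_dir, "genome.fa"))
  writeLines(gtf, file.path(out_dir, "transcripts.gtf"))
  utils::write.table(xref, file.path(out_dir, "crossref.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vcf <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=FX,Number=0,Type=Flag,Description=\"Planted fixture variant\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  if (!is.null(variants)) {
    vo <- variants[order(variants$chrom, variants$g_pos), , drop = FALSE]
    alt_field <- vo$g_alt
    multi <- seq_len(nrow(vo)) %% 7L == 0L  # some multi-allelic records
    extra <- vapply(which(multi), function(k)
      setdiff(c("A", "C", "G", "T"), c(vo$g_ref[k], vo$g_alt[k]))[1L],
      character(1))
    alt_field[multi] <- paste(alt_field[multi], extra, sep = ",")
    vcf <- c(vcf, paste(vo$chrom, vo$g_pos, vo$rsid, vo$g_ref, alt_field,
                        ".", "PASS", "FX", sep = "\t"))
  }
  writeLines(vcf, file.path(out_dir, "dbsnp.vcf"))
  if (!is.null(panel))
    utils::write.table(panel,
                       file.path(out_dir, "panel_db_gnomAD_exome_freq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  writeLines(c("species=hsapiens",
               "gtf=transcripts.gtf", "fasta=genome.fa",
               "crossref=crossref.tsv", "dbsnp=dbsnp.vcf",
               "default_panel=db_gnomAD_exome_freq",
               "panel.db_gnomAD_exome_freq.path=panel_db_gnomAD_exome_freq.tsv",
               "panel.db_gnomAD_exome_freq.format=tsv"),
             file.path(out_dir, "bundle.ini"))
  utils::write.csv(do.call(rbind, pbm_rows),
                   file.path(out_dir, "gold_per_base_map.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(variants)) {
    utils::write.csv(data.frame(Transcript_version = variants$refseq,
                                Nucleotide_changes = sprintf("%s%d%s",
                                                             variants$ref,
                                                             variants$cds_pos,
                                                             variants$alt)),
                     file.path(out_dir, "transcript_changes.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(Chr = variants$chrom, Start = variants$g_pos,
                                End = variants$g_pos, Ref = variants$g_ref,
                                Alt = variants$g_alt),
                     file.path(out_dir, "variants.csv"),
                     row.names = FALSE, quote = FALSE)
    gold_conv <- data.frame(
      Transcript_version = variants$refseq,
      Nucleotide_changes = sprintf("%s%d%s", variants$ref, variants$cds_pos,
                                   variants$alt),
      CDS_start_loc = variants$cds_pos, Ref = variants$ref, Alt = variants$alt,
      Chr = variants$chrom, ensembl_transcript_id = variants$tid,
      hgnc_symbol = variants$gene, start = variants$g_pos,
      end = variants$g_pos, width = 1L, strand = variants$strand,
      exon_id = variants$exon_id, exon_rank = variants$exon_rank,
      tx_start = variants$tx_pos, tx_end = variants$tx_pos,
      refsnp_id = variants$rsid, stringsAsFactors = FALSE)
    utils::write.csv(gold_conv, file.path(out_dir, "gold_conversion.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(Chr = variants$chrom, Start = variants$g_pos,
                                End = variants$g_pos, Ref = variants$g_ref,
                                Alt = variants$g_alt,
                                codon_number = variants$codon,
                                ref_aa = variants$ref_aa,
                                alt_aa = variants$alt_aa,
                                ExonicFunc = variants$class,
                                Gene = variants$gene,
                                in_panel = variants$in_panel),
                     file.path(out_dir, "gold_consequence.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(dir = out_dir, truth = truth, variants = variants))
}
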
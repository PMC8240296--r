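# A small worked-example bundle: synthetic reconstructions of two human
# transcript models, SMAD4 ENST00000342988 (plus a second SMAD4 isoform)
# and BRCA2 ENST00000544455, on GRCh37. The exon scaffolds are invented,
# but every quantity that matters to the worked example is pinned to
# published annotation facts: the 5'UTR lengths (538 and 227 nt), the
# exon ranks and exon IDs holding the example variants, the genomic
# anchor positions on chr18/chr13, and the amino acids at the example
# codons (N316/N161 in SMAD4, Q1037/K1533 in BRCA2). Within the anchored
# exons the transcript-to-genome offset is constant, so the example
# mappings are exact even though the surrounding scaffold is synthetic.
#
# Two layouts:
#  * "grch37"  - true chr18/chr13 coordinates, no genome FASTA (the ID
#                conversion and rsID lookup paths need none);
#  * "compact" - the same models shifted near the origin with a small
#                invented genome realising the example codons, so the
#                consequence and frequency paths run end to end.

demo_codons <- function(n, fixed) {
  # codon 1 ATG, last codon TGA, the rest non-stop; `fixed` overrides
  stops <- c("TAA", "TAG", "TGA")
  pool <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")), 1L, paste,
                        collapse = ""), stops)
  codons <- c("ATG", sample(pool, n - 2L, replace = TRUE), "TGA")
  for (k in names(fixed)) codons[as.integer(k)] <- fixed[[k]]
  codons
}

demo_exon_coords <- function(widths, anchor_idx, anchor_start, intron = 500L) {
  n <- length(widths)
  g_start <- g_end <- integer(n)
  g_start[anchor_idx] <- anchor_start
  g_end[anchor_idx] <- anchor_start + widths[anchor_idx] - 1L
  for (k in rev(seq_len(anchor_idx - 1L))) {
    g_end[k] <- g_start[k + 1L] - intron - 1L
    g_start[k] <- g_end[k] - widths[k] + 1L
  }
  for (k in (anchor_idx + 1L):n) {
    if (k > n) break
    g_start[k] <- g_end[k - 1L] + intron + 1L
    g_end[k] <- g_start[k] + widths[k] - 1L
  }
  data.frame(g_start = g_start, g_end = g_end)
}

demo_gtf_lines <- function(chrom, tid, gene, coords, exon_ids, utr5, cds_len) {
  n <- nrow(coords)
  lines <- vapply(seq_len(n), function(k) {
    paste(chrom, "txvardemo", "exon", coords$g_start[k], coords$g_end[k], ".",
          "+", ".",
          sprintf('transcript_id "%s"; gene_name "%s"; exon_number "%d"; exon_id "%s";',
                  tid, gene, k, exon_ids[k]), sep = "\t")
  }, character(1))
  pbm <- unlist(lapply(seq_len(n), function(k) coords$g_start[k]:coords$g_end[k]))
  cds_g <- sort(pbm[(utr5 + 1L):(utr5 + cds_len)])
  brk <- c(0L, which(diff(cds_g) != 1L), length(cds_g))
  for (b in seq_len(length(brk) - 1L)) {
    seg <- cds_g[(brk[b] + 1L):brk[b + 1L]]
    lines <- c(lines, paste(chrom, "txvardemo", "CDS", seg[1L], seg[length(seg)],
                            ".", "+", "0",
                            sprintf('transcript_id "%s"; gene_name "%s";', tid, gene),
                            sep = "\t"))
  }
  lines
}

#' Write the synthetic two-gene demonstration bundle
#'
#' See the file-level notes: SMAD4 (two isoforms) and BRCA2 models whose
#' anchored exons reproduce the published variant mappings
#' (chr18:48,586,278, chr13:32,911,601, chr13:32,913,091; transcript
#' positions 1485, 3336, 4826) exactly. The `"compact"` layout shifts
#' chr18 by -48,580,000 and chr13 by -32,900,000 and adds a genome plus a
#' gnomAD-exome-style panel so consequence and frequency annotation run.
#'
#' @param dir Output directory (created if needed).
#' @param layout `"grch37"` (true coordinates, no genome) or `"compact"`.
#' @return Invisibly, `dir`.
#' @export
demo_pdac_bundle <- function(dir, layout = c("grch37", "compact")) {
  layout <- match.arg(layout)
  set.seed(20210628L)  # fixed: the demo is one deterministic object
  shift18 <- if (layout == "compact") 48580000L else 0L
  shift13 <- if (layout == "compact") 32900000L else 0L

  # SMAD4 isoform 1 (ENST00000342988): site tx 1485 = CDS 947 in exon 8
  w1 <- c(600L, 200L, 150L, 100L, 120L, 90L, 140L, 300L, 250L, 180L, 200L, 400L)
  utr5_1 <- 538L; n_cod1 <- 553L  # CDS 1659 nt incl. stop
  co1 <- demo_exon_coords(w1, anchor_idx = 8L, anchor_start = 48586194L - shift18)
  cod1 <- demo_codons(n_cod1, list("316" = "AAT"))
  cds1 <- paste(cod1, collapse = "")
  ids1 <- sprintf("SMAD4AE%02d", seq_along(w1)); ids1[8L] <- "ENSE00003494728"

  # SMAD4 isoform 2: exons 5..12 of isoform 1, rank-1 exon extended 100 bp
  # upstream; same genomic site is CDS 482 in its exon 4 (frame-aligned:
  # isoform-2 codon c = isoform-1 codon c + 155 for c >= 17)
  w2 <- c(w1[5L] + 100L, w1[6:12])
  co2 <- data.frame(g_start = c(co1$g_start[5L] - 100L, co1$g_start[6:12]),
                    g_end = co1$g_end[5:12])
  utr5_2 <- 53L
  prefix47 <- paste0("ATG", paste(demo_codons(16L, list())[2:15], collapse = ""), "GG")
  cds2 <- paste0(prefix47, substr(cds1, 513L, nchar(cds1)))
  ids2 <- sprintf("SMAD4BE%02d", seq_along(w2))

  # BRCA2 (ENST00000544455): tx 3336 and 4826 both in exon 11
  w3 <- c(200L, 150L, 120L, 100L, 90L, 110L, 130L, 140L, 160L, 180L, 5000L,
          2000L, 1500L, 800L)
  utr5_3 <- 227L; n_cod3 <- 3419L  # CDS 10257 nt incl. stop
  co3 <- demo_exon_coords(w3, anchor_idx = 11L, anchor_start = 32909646L - shift13)
  cod3 <- demo_codons(n_cod3, list("1037" = "CAA", "1533" = "AAA"))
  cds3 <- paste(cod3, collapse = "")
  ids3 <- sprintf("BRCA2E%02d", seq_along(w3)); ids3[11L] <- "ENSE00000939168"

  tid1 <- "ENST00000342988"; tid2 <- "ENSTSYN0SMAD4B"; tid3 <- "ENST00000544455"
  gtf <- c(
    demo_gtf_lines("18", tid2, "SMAD4", co2, ids2, utr5_2, nchar(cds2)),
    demo_gtf_lines("18", tid1, "SMAD4", co1, ids1, utr5_1, nchar(cds1)),
    demo_gtf_lines("13", tid3, "BRCA2", co3, ids3, utr5_3, nchar(cds3)))

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(gtf, file.path(dir, "transcripts.gtf"))

  xref <- data.frame(
    refseq_id = c("NM_005359", "", "NM_000059"),
    ucsc_id = c("uc010xdp.2", "uc002lfb.4", "uc001uub.1"),
    ensembl_transcript_id = c(tid1, tid2, tid3),
    hgnc_symbol = c("SMAD4", "SMAD4", "BRCA2"),
    canonical_flag = c("true", "false", "true"), stringsAsFactors = FALSE)
  utils::write.table(xref, file.path(dir, "crossref.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  site18 <- 48586278L - shift18
  site13a <- 32911601L - shift13
  site13b <- 32913091L - shift13
  vcf <- c("##fileformat=VCFv4.2",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"),
           paste("13", site13a, "rs80358557", "C", "T", ".", "PASS", ".", sep = "\t"),
           paste("13", site13b, "rs80358694", "A", "C", ".", "PASS", ".", sep = "\t"),
           paste("18", site18, "rs377119288", "A", "G", ".", "PASS", ".", sep = "\t"))
  writeLines(vcf, file.path(dir, "dbsnp.vcf"))

  utils::write.csv(data.frame(
    Transcript_version = c("NM_005359", "NM_000059", "NM_000059"),
    Nucleotide_changes = c("A947G", "C3109T", "A4599C")),
    file.path(dir, "transcript_changes.csv"), row.names = FALSE, quote = FALSE)

  ini <- c("species=hsapiens", "gtf=transcripts.gtf", "crossref=crossref.tsv",
           "dbsnp=dbsnp.vcf", "default_panel=db_gnomAD_exome_freq")
  if (layout == "compact") {
    # plant the genome: isoform-1/BRCA2 exon chunks, then the isoform-2
    # 100-bp extension (53 nt UTR + 47 nt CDS prefix) in intron 4
    plant <- function(len, coords, tx_seq) {
      g <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      cum <- cumsum(coords$g_end - coords$g_start + 1L)
      prev <- c(0L, cum[-length(cum)])
      for (k in seq_len(nrow(coords)))
        g[coords$g_start[k]:coords$g_end[k]] <-
          strsplit(substr(tx_seq, prev[k] + 1L, cum[k]), "")[[1L]]
      g
    }
    txseq1 <- paste0(rand_bases(utr5_1), cds1,
                     rand_bases(sum(w1) - utr5_1 - nchar(cds1)))
    txseq3 <- paste0(rand_bases(utr5_3), cds3,
                     rand_bases(sum(w3) - utr5_3 - nchar(cds3)))
    g18 <- plant(max(co1$g_end) + 100L, co1, txseq1)
    ext <- paste0(rand_bases(utr5_2), prefix47)
    g18[(co1$g_start[5L] - 100L):(co1$g_start[5L] - 1L)] <- strsplit(ext, "")[[1L]]
    g13 <- plant(max(co3$g_end) + 100L, co3, txseq3)
    writeLines(c(">18", paste(g18, collapse = ""),
                 ">13", paste(g13, collapse = "")),
               file.path(dir, "genome.fa"))
    # panel values mirror the published worked example: two variants with
    # rare alternate alleles in a few subpopulations, one panel-absent
    panel <- data.frame(Chr = c("18", "13"), Pos = c(site18, site13b),
                        Ref = c("A", "A"), Alt = c("G", "C"),
                        stringsAsFactors = FALSE)
    afcols <- list(AF_ALL = c(1e-4, 1e-4), AF_AFR = c(NA, NA),
                   AF_AMR = c(NA, NA), AF_ASJ = c(NA, NA),
                   AF_EAS = c(1e-4, 0.0013), AF_FIN = c(NA, NA),
                   AF_NFE = c(3e-4, NA), AF_SAS = c(NA, NA),
                   AF_OTH = c(1e-4, NA))
    for (nm in names(afcols)) panel[[nm]] <- afcols[[nm]]
    utils::write.table(panel, file.path(dir, "panel_db_gnomAD_exome_freq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    utils::write.csv(data.frame(Chr = c("18", "13", "13"),
                                Start = c(site18, site13a, site13b),
                                End = c(site18, site13a, site13b),
                                Ref = c("A", "C", "A"), Alt = c("G", "T", "C")),
                     file.path(dir, "variants.csv"), row.names = FALSE,
                     quote = FALSE)
    ini <- c(ini, "fasta=genome.fa",
             "panel.db_gnomAD_exome_freq.path=panel_db_gnomAD_exome_freq.tsv",
             "panel.db_gnomAD_exome_freq.format=tsv")
  }
  writeLines(ini, file.path(dir, "bundle.ini"))
  invisible(dir)
}
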
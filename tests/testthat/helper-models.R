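# Hand-built toy models and a planted toy genome, used across the suite.
#
# TX1: chrT, plus strand, exons 101-150 / 201-260 / 301-340 (transcript
#      length 150), CDS at transcript 11-130 (120 nt = 40 codons), the CDS
#      planted as 40 repeats of "ATG".
# TX2: chrT, minus strand, exons in transcript order 601-650 then 451-500
#      (length 100), CDS at transcript 11-70 (20 codons) with known codons
#      at the start for consequence spot checks.

tx1_model <- function() {
  new_tx_model("TX1", "GENE1", "chrT", "+",
               data.frame(exon_id = c("TX1.E1", "TX1.E2", "TX1.E3"),
                          g_start = c(101L, 201L, 301L),
                          g_end = c(150L, 260L, 340L), rank = 1:3),
               cds_tx_start = 11L, cds_tx_end = 130L)
}

tx2_model <- function() {
  new_tx_model("TX2", "GENE2", "chrT", "-",
               data.frame(exon_id = c("TX2.E1", "TX2.E2"),
                          g_start = c(601L, 451L), g_end = c(650L, 500L),
                          rank = 1:2),
               cds_tx_start = 11L, cds_tx_end = 70L)
}

tx1_cds <- function() strrep("ATG", 40L)

# ATG | CAA | AAA | CTG then 15 GCA (Ala) codons and TAA stop = 20 codons
tx2_cds <- function() paste0("ATG", "CAA", "AAA", "CTG", strrep("GCA", 15L), "TAA")

tx1_txseq <- function() paste0(strrep("T", 10L), tx1_cds(), strrep("C", 20L))
tx2_txseq <- function() paste0(strrep("T", 10L), tx2_cds(), strrep("C", 30L))

# plant a transcript sequence into a character-vector genome (naive)
plant_tx <- function(gchar, model, txseq) {
  w <- model$exons$g_end - model$exons$g_start + 1L
  cum <- cumsum(w); prev <- c(0L, cum[-length(cum)])
  for (k in seq_len(nrow(model$exons))) {
    chunk <- substr(txseq, prev[k] + 1L, cum[k])
    if (model$strand == "-")
      chunk <- paste(rev(strsplit(chartr("ACGT", "TGCA", chunk), "")[[1L]]),
                     collapse = "")
    gchar[model$exons$g_start[k]:model$exons$g_end[k]] <-
      strsplit(chunk, "")[[1L]]
  }
  gchar
}

toy_genome <- function() {
  set.seed(7L)
  gchar <- sample(c("A", "C", "G", "T"), 800L, replace = TRUE)
  gchar <- plant_tx(gchar, tx1_model(), tx1_txseq())
  gchar <- plant_tx(gchar, tx2_model(), tx2_txseq())
  g <- Biostrings::DNAStringSet(paste(gchar, collapse = ""))
  names(g) <- "chrT"
  g
}

# build a coding model + single-chromosome genome from explicit pieces;
# used for the exhaustive consequence sweeps
make_planted_tx <- function(tid, strand, widths, utr5, cds, utr3_min = 5L,
                            seed = 11L) {
  set.seed(seed)
  total_needed <- utr5 + nchar(cds) + utr3_min
  if (sum(widths) < total_needed)
    widths[length(widths)] <- widths[length(widths)] + total_needed - sum(widths)
  utr3 <- sum(widths) - utr5 - nchar(cds)
  txseq <- paste0(paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
                        collapse = ""), cds,
                  paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE),
                        collapse = ""))
  n <- length(widths)
  introns <- rep(50L, max(n - 1L, 0L))
  g_start <- g_end <- integer(n)
  span <- sum(widths) + sum(introns)
  if (strand == "+") {
    cur <- 101L
    for (k in seq_len(n)) {
      g_start[k] <- cur; g_end[k] <- cur + widths[k] - 1L
      cur <- g_end[k] + (if (k < n) introns[k] else 0L) + 1L
    }
  } else {
    cur <- 100L + span
    for (k in seq_len(n)) {
      g_end[k] <- cur; g_start[k] <- cur - widths[k] + 1L
      cur <- g_start[k] - (if (k < n) introns[k] else 0L) - 1L
    }
  }
  model <- new_tx_model(tid, paste0(tid, "_GENE"), "chrP", strand,
                        data.frame(exon_id = sprintf("%s.E%d", tid, seq_len(n)),
                                   g_start = g_start, g_end = g_end,
                                   rank = seq_len(n)),
                        cds_tx_start = utr5 + 1L,
                        cds_tx_end = utr5 + nchar(cds))
  gchar <- sample(c("A", "C", "G", "T"), 100L + span + 100L, replace = TRUE)
  gchar <- plant_tx(gchar, model, txseq)
  genome <- Biostrings::DNAStringSet(paste(gchar, collapse = ""))
  names(genome) <- "chrP"
  list(model = model, genome = genome, txseq = txseq)
}
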
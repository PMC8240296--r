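# Loading and indexing of transcript models, crossrefs and genome files.

write_tx1_gtf <- function(path) {
  # TX1 with CDS at transcript 11-130: genomic CDS pieces 111-150,
  # 201-260, 301-320
  at <- 'transcript_id "TX1"; gene_name "GENE1"; exon_number "%d"; exon_id "TX1.E%d";'
  ac <- 'transcript_id "TX1"; gene_name "GENE1";'
  writeLines(c(
    paste("chrT", "t", "exon", 101, 150, ".", "+", ".", sprintf(at, 1, 1), sep = "\t"),
    paste("chrT", "t", "exon", 201, 260, ".", "+", ".", sprintf(at, 2, 2), sep = "\t"),
    paste("chrT", "t", "exon", 301, 340, ".", "+", ".", sprintf(at, 3, 3), sep = "\t"),
    paste("chrT", "t", "CDS", 111, 150, ".", "+", "0", ac, sep = "\t"),
    paste("chrT", "t", "CDS", 201, 260, ".", "+", "0", ac, sep = "\t"),
    paste("chrT", "t", "CDS", 301, 320, ".", "+", "0", ac, sep = "\t")), path)
  path
}

test_that("GTF loading derives exon order, lengths and the CDS span", {
  gtf <- write_tx1_gtf(tempfile(fileext = ".gtf"))
  models <- load_transcript_models(gtf)
  expect_named(models, "TX1")
  m <- models$TX1
  expect_equal(nrow(m$exons), 3L)
  expect_equal(transcript_length(m), 150L)
  expect_true(is_coding(m))
  expect_equal(m$cds_tx_start, 11L)
  expect_equal(m$cds_tx_end, 130L)
  expect_equal(cds_length(m), 120L)
  expect_false(m$cds_incomplete)
  expect_equal(m$gene_symbol, "GENE1")
})

test_that("exon-only transcripts load as non-coding and are kept", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chrT", "t", "exon", 101, 160, ".", "+", ".",
                   'transcript_id "TXnc"; gene_name "GENEnc";', sep = "\t"), gtf)
  models <- load_transcript_models(gtf)
  expect_false(is_coding(models$TXnc))
  expect_true(is.na(models$TXnc$cds_tx_start))
  expect_error(cds_to_transcript(models$TXnc, 1L), "non-coding")
})

test_that("a CDS segment outside every exon is a model-consistency error", {
  gtf <- write_tx1_gtf(tempfile(fileext = ".gtf"))
  lines <- readLines(gtf)
  writeLines(c(lines, paste("chrT", "t", "CDS", 400, 410, ".", "+", "0",
                            'transcript_id "TX1"; gene_name "GENE1";',
                            sep = "\t")), gtf)
  expect_error(load_transcript_models(gtf), "model-consistency.*TX1")
})

test_that("malformed GTF lines are reported with their line number", {
  gtf <- write_tx1_gtf(tempfile(fileext = ".gtf"))
  lines <- readLines(gtf)
  writeLines(c(lines[1:2], "chrT exon broken-line", lines[3:6]), gtf)
  expect_error(load_transcript_models(gtf), "line 3")
})

test_that("refFlat input yields the same model as the equivalent GTF", {
  gtf_m <- load_transcript_models(write_tx1_gtf(tempfile(fileext = ".gtf")))$TX1
  rf <- tempfile(fileext = ".txt")
  # refFlat is 0-based half-open: exon/CDS starts shift down by one
  writeLines(paste("GENE1", "TX1", "chrT", "+", 100, 340, 110, 320, 3,
                   "100,200,300,", "150,260,340,", sep = "\t"), rf)
  rf_m <- load_refflat(rf)$TX1
  expect_equal(rf_m$exons$g_start, gtf_m$exons$g_start)
  expect_equal(rf_m$exons$g_end, gtf_m$exons$g_end)
  expect_equal(rf_m$cds_tx_start, gtf_m$cds_tx_start)
  expect_equal(rf_m$cds_tx_end, gtf_m$cds_tx_end)
})

test_that("crossref lookup resolves all three namespaces, with and without version", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("refseq_id\tucsc_id\tensembl_transcript_id\thgnc_symbol",
               "NM_005359\tuc010xdp.2\tENST00000342988\tSMAD4"), tsv)
  xr <- load_crossref(tsv)
  expect_equal(crossref_lookup(xr, "NM_005359")$ensembl_transcript_id,
               "ENST00000342988")
  expect_equal(crossref_lookup(xr, "uc010xdp.2")$ensembl_transcript_id,
               "ENST00000342988")
  expect_equal(crossref_lookup(xr, "NM_005359.4")$ensembl_transcript_id,
               "ENST00000342988")
  expect_equal(nrow(crossref_lookup(xr, "NM_999999")), 0L)
})

test_that("conflicting versioned crossref keys are a load error", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("refseq_id\tucsc_id\tensembl_transcript_id\thgnc_symbol",
               "NM_1.1\tucA.1\tENST_A\tG1",
               "NM_1.1\tucB.1\tENST_B\tG1"), tsv)
  expect_error(load_crossref(tsv), "conflicting.*NM_1.1")
})

test_that("resolve_transcript tie-breaks deterministically and reports failures", {
  dummy <- function(tid) new_tx_model(tid, "G", "chrT", "+",
                                      data.frame(exon_id = "e", g_start = 1L,
                                                 g_end = 30L, rank = 1L))
  models <- list(ENST_B = dummy("ENST_B"), ENST_A = dummy("ENST_A"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("refseq_id\tucsc_id\tensembl_transcript_id\thgnc_symbol\tcanonical_flag",
               "NM_X\tucX.1\tENST_A\tG\tfalse",
               "NM_X\tucY.1\tENST_B\tG\ttrue",
               "NM_GONE\tucZ.1\tENST_MISSING\tG\tfalse"), tsv)
  xr <- load_crossref(tsv)
  # canonical wins over lexicographic order
  expect_message(m <- resolve_transcript("NM_X", xr, models), "ENST_B")
  expect_equal(m$transcript_id, "ENST_B")
  # versionless query resolves identically (determinism across calls)
  m2 <- suppressMessages(resolve_transcript("NM_X.3", xr, models))
  expect_equal(m2$transcript_id, m$transcript_id)
  # without canonical flags the lexicographically smallest id wins
  xr$table$canonical_flag <- FALSE
  expect_equal(suppressMessages(resolve_transcript("NM_X", xr, models))$transcript_id,
               "ENST_A")
  # Ensembl ids bypass the crossref
  expect_equal(resolve_transcript("ENST_A", xr, models)$transcript_id, "ENST_A")
  expect_error(resolve_transcript("NM_NOPE", xr, models), "unresolved")
  expect_error(resolve_transcript("NM_GONE", xr, models), "missing-model")
})

test_that("loaded bundle models satisfy the structural invariants", {
  b <- bundle42()
  for (m in b$models) {
    expect_equal(sum(m$exons$g_end - m$exons$g_start + 1L),
                 transcript_length(m))
    if (is_coding(m)) {
      expect_lte(m$cds_tx_end, transcript_length(m))
      expect_equal(cds_length(m) %% 3L, 0L)
      expect_false(m$cds_incomplete)
    }
  }
})

test_that("models survive a GTF serialisation roundtrip field-by-field", {
  b <- bundle42()
  out <- tempfile(fileext = ".gtf")
  write_models_gtf(b$models, out)
  reloaded <- load_transcript_models(out)
  expect_setequal(names(reloaded), names(b$models))
  for (tid in names(b$models)) {
    m0 <- b$models[[tid]]; m1 <- reloaded[[tid]]
    expect_identical(m1$exons$g_start, m0$exons$g_start)
    expect_identical(m1$exons$g_end, m0$exons$g_end)
    expect_identical(m1$exons$exon_id, m0$exons$exon_id)
    expect_identical(m1$strand, m0$strand)
    expect_identical(m1$chrom, m0$chrom)
    expect_identical(m1$cds_tx_start, m0$cds_tx_start)
    expect_identical(m1$cds_tx_end, m0$cds_tx_end)
  }
})
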
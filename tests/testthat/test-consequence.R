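# CDS splicing, codon/amino-acid consequence calls and region classes.
# The exhaustive sweep compares the codon-arithmetic implementation with
# the naive oracle that rebuilds and diffs the whole mutant protein.

test_that("spliced_cds_sequence extracts the planted CDS on both strands", {
  g <- toy_genome()
  expect_equal(spliced_cds_sequence(tx1_model(), g), tx1_cds())
  expect_equal(spliced_cds_sequence(tx2_model(), g), tx2_cds())
  nc <- new_tx_model("TXnc", "G", "chrT", "+",
                     data.frame(exon_id = "e", g_start = 700L, g_end = 750L,
                                rank = 1L))
  expect_error(spliced_cds_sequence(nc, g), "non-coding")
})

test_that("consequence calls classify the canonical change types", {
  g <- toy_genome()
  m2 <- tx2_model()
  # codon 2 CAA, first base C>T -> TAA stopgain (Q -> stop)
  sg <- annotate_consequence(m2, g, list(ref = "C", cds_pos = 4L, alt = "T"))
  expect_equal(sg$codon_number, 2L)
  expect_equal(sg$pos_in_codon, 1L)
  expect_equal(sg$ref_codon, "CAA"); expect_equal(sg$alt_codon, "TAA")
  expect_equal(sg$ref_aa, "Q"); expect_equal(sg$alt_aa, "X")
  expect_equal(sg$exonic_function, "stopgain")
  expect_false(sg$ref_mismatch)
  # codon 3 AAA, third base A>C -> AAC, K -> N missense
  ns <- annotate_consequence(m2, g, list(ref = "A", cds_pos = 9L, alt = "C"))
  expect_equal(ns$exonic_function, "nonsynonymous SNV")
  expect_equal(ns$ref_aa, "K"); expect_equal(ns$alt_aa, "N")
  # codon 4 CTG -> CTA stays leucine
  syn <- annotate_consequence(m2, g, list(ref = "G", cds_pos = 12L, alt = "A"))
  expect_equal(syn$exonic_function, "synonymous SNV")
  # stop codon TAA -> TAC gains tyrosine: stoploss
  sl <- annotate_consequence(m2, g, list(ref = "A", cds_pos = 60L, alt = "C"))
  expect_equal(sl$exonic_function, "stoploss")
  # disrupting the start ATG
  st <- annotate_consequence(tx1_model(), g, list(ref = "T", cds_pos = 2L, alt = "C"))
  expect_equal(st$exonic_function, "startloss")
})

test_that("aachange strings and genome-strand alleles are strand-correct", {
  g <- toy_genome()
  m2 <- tx2_model()
  sg <- annotate_consequence(m2, g, list(ref = "C", cds_pos = 4L, alt = "T"))
  expect_equal(sg$aachange, "GENE2:TX2:exon1:c.C4T:p.Q2X")
  # minus strand: genome-plus alleles are complemented
  expect_equal(sg$g_ref, "G"); expect_equal(sg$g_alt, "A")
  # and the genome base at the projected position equals g_ref
  loc <- sg$locus
  expect_equal(as.character(Biostrings::subseq(g[["chrT"]], loc$g_start,
                                               loc$g_start)), sg$g_ref)
  p <- annotate_consequence(tx1_model(), g, list(ref = "G", cds_pos = 6L, alt = "A"))
  expect_equal(p$g_ref, "G")  # plus strand passes through
})

test_that("a genome/declared-reference disagreement flags, not fails", {
  g <- toy_genome()
  res <- annotate_consequence(tx1_model(), g,
                              list(ref = "C", cds_pos = 1L, alt = "G"))
  expect_true(res$ref_mismatch)
  expect_error(annotate_consequence(tx1_model(), g,
                                    list(ref = "A", cds_pos = 121L, alt = "G")),
               "out-of-CDS")
})

test_that("exhaustive substitutions of a 120-codon transcript match the protein-diff oracle", {
  set.seed(33L)
  stops <- c("TAA", "TAG", "TGA")
  pool <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")), 1L, paste,
                        collapse = ""), stops)
  cds <- paste0("ATG", paste(sample(pool, 118L, replace = TRUE), collapse = ""),
                "TAA")
  tx <- make_planted_tx("TX120", "+", widths = c(150L, 160L, 200L),
                        utr5 = 25L, cds = cds)
  bases <- c("A", "C", "G", "T")
  n_checked <- 0L
  for (p in seq_len(360L)) {
    ref <- substr(cds, p, p)
    for (alt in setdiff(bases, ref)) {
      got <- annotate_consequence(tx$model, tx$genome,
                                  list(ref = ref, cds_pos = p, alt = alt))
      oracle <- txvar:::naive_classify(cds, p, alt)
      expect_identical(got$exonic_function, oracle$class)
      expect_identical(got$codon_number, oracle$codon)
      if (oracle$class == "synonymous SNV") {
        mut <- cds; substr(mut, p, p) <- alt
        expect_identical(txvar:::naive_translate(mut),
                         txvar:::naive_translate(cds))
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_identical(n_checked, 1080L)
})

test_that("minus-strand consequences equal the oracle on complemented genome alleles", {
  set.seed(34L)
  stops <- c("TAA", "TAG", "TGA")
  pool <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")), 1L, paste,
                        collapse = ""), stops)
  cds <- paste0("ATG", paste(sample(pool, 40L, replace = TRUE), collapse = ""),
                "TGA")
  tx <- make_planted_tx("TXm", "-", widths = c(80L, 90L), utr5 = 12L, cds = cds)
  bases <- c("A", "C", "G", "T")
  for (p in seq_len(nchar(cds))) {
    ref <- substr(cds, p, p)
    for (alt in setdiff(bases, ref)) {
      ch <- list(ref = ref, cds_pos = p, alt = alt)
      got <- annotate_consequence(tx$model, tx$genome, ch)
      expect_false(got$ref_mismatch)
      expect_identical(got$exonic_function, txvar:::naive_classify(cds, p, alt)$class)
      # genome-strand allele at the projected locus is the complement
      loc <- transcript_to_genomic(tx$model, cds_to_transcript(tx$model, p))
      gbase <- as.character(Biostrings::subseq(tx$genome[["chrP"]],
                                               loc$g_start, loc$g_start))
      expect_identical(gbase, chartr("ACGT", "TGCA", ref))
      expect_identical(got$g_ref, gbase)
    }
  }
})

test_that("region classification follows the documented priority rules", {
  models <- list(TX1 = tx1_model(), TX2 = tx2_model())
  idx <- build_region_index(models)
  cls <- function(pos) classify_region(idx, list(chrom = "chrT", g_start = pos))
  expect_equal(cls(205L)$region, "exonic")        # TX1 CDS base
  expect_equal(cls(205L)$genes, "GENE1")
  expect_equal(cls(103L)$region, "UTR5")          # tx 3 < CDS start 11
  expect_equal(cls(335L)$region, "UTR3")          # tx 145 > CDS end 130
  expect_equal(cls(152L)$region, "splicing")      # 2 bp past exon 1 end
  expect_equal(cls(155L)$region, "intronic")
  expect_equal(cls(50000L)$region, "intergenic")
  expect_length(cls(50000L)$genes, 0L)
  # minus-strand UTRs: tx coords are strand-aware, genomic 650 is tx 1
  expect_equal(cls(645L)$region, "UTR5")          # TX2 tx 6 < 11
  expect_equal(cls(455L)$region, "UTR3")          # TX2 tx 96 > 70
})
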
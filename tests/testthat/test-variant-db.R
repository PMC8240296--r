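# rsID lookup and frequency-panel annotation.

write_vcf <- function(path, rows) {
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"), rows), path)
  path
}

test_that("rsID lookup requires ref equality and alt membership", {
  vcf <- write_vcf(tempfile(fileext = ".vcf"), c(
    paste("chrT", 111, "rsF0001", "A", "G", ".", "PASS", ".", sep = "\t"),
    paste("chrT", 120, "rsF0002", "A", "G,T", ".", "PASS", ".", sep = "\t")))
  db <- load_snp_vcf(vcf)
  v <- function(pos, ref, alt) list(chrom = "chrT", g_start = pos, ref = ref,
                                    alt = alt)
  expect_equal(lookup_rsid(db, v(111L, "A", "G")), "rsF0001")
  expect_equal(lookup_rsid(db, v(111L, "A", "C")), "")  # alt not listed
  expect_equal(lookup_rsid(db, v(111L, "C", "G")), "")  # ref mismatch
  expect_equal(lookup_rsid(db, v(112L, "A", "G")), "")  # position miss
  # multi-allelic record matches any of its alternates
  expect_equal(lookup_rsid(db, v(120L, "A", "T")), "rsF0002")
})

test_that("an unsorted dbSNP VCF is rejected at load", {
  vcf <- write_vcf(tempfile(fileext = ".vcf"), c(
    paste("chrT", 120, "rsB", "A", "G", ".", "PASS", ".", sep = "\t"),
    paste("chrT", 111, "rsA", "A", "G", ".", "PASS", ".", sep = "\t")))
  expect_error(load_snp_vcf(vcf), "index error")
})

test_that("unknown panel names are a configuration error listing options", {
  expect_error(frequency_panel("db_nope"), "unknown panel.*db_gnomAD_exome_freq")
  expect_equal(frequency_panel("db_1000Genomes_5pop_freq")$subpops,
               c("EAS", "AMR", "AFR", "EUR", "SAS"))
})

test_that("frequency annotation complements, defaults absents to (1,0) and is total", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(paste("Chr", "Pos", "Ref", "Alt", "AF_ALL", "AF_AFR", sep = "\t"),
               paste("chrT", 111, "A", "G", "1e-4", "", sep = "\t"),
               paste("chrT", 150, "C", "T", "0.5", "0.25", sep = "\t")), tsv)
  panel <- frequency_panel("toy_panel", path = tsv, subpops = c("ALL", "AFR"))
  variants <- data.frame(chrom = "chrT", g_start = c(111L, 150L, 999L),
                         g_end = c(111L, 150L, 999L),
                         ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                         stringsAsFactors = FALSE)
  ann <- annotate_frequencies(variants, panel)
  expect_equal(nrow(ann), 3L)  # total regardless of panel hits
  expect_equal(ann$toy_panel_ALL_Ref_freq[1L], 0.9999)
  expect_equal(ann$toy_panel_ALL_Alt_freq[1L], 1e-4)
  # subpop cell absent in a present record also defaults to (1, 0)
  expect_equal(ann$toy_panel_AFR_Ref_freq[1L], 1)
  expect_equal(ann$toy_panel_AFR_Alt_freq[1L], 0)
  expect_equal(ann$toy_panel_ALL_Ref_freq[2L], 0.5)
  expect_equal(ann$toy_panel_ALL_Alt_freq[2L], 0.5)
  # variant absent from the panel: (1, 0) everywhere
  expect_equal(ann$toy_panel_ALL_Ref_freq[3L], 1)
  expect_equal(ann$toy_panel_ALL_Alt_freq[3L], 0)
  expect_equal(ann$toy_panel_AFR_Alt_freq[3L], 0)
})

test_that("VCF-backed panels read per-population AF INFO keys", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
               "##INFO=<ID=AF_afr,Number=A,Type=Float,Description=\"AFR AF\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               paste("chrT", 111, ".", "A", "G", ".", "PASS",
                     "AF=0.0001;AF_afr=0.2", sep = "\t")), vcf)
  panel <- frequency_panel("vpanel", path = vcf, subpops = c("ALL", "AFR"),
                           format = "vcf")
  variants <- data.frame(chrom = "chrT", g_start = 111L, g_end = 111L,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  ann <- annotate_frequencies(variants, panel)
  expect_equal(ann$vpanel_ALL_Alt_freq, 1e-4)
  expect_equal(ann$vpanel_AFR_Alt_freq, 0.2)
})

test_that("MAF is min(Ref_freq, Alt_freq) and never exceeds 0.5", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(paste("Chr", "Pos", "Ref", "Alt", "AF_ALL", sep = "\t"),
               paste("chrT", 111, "A", "G", "1e-4", sep = "\t"),
               paste("chrT", 150, "C", "T", "0.6", sep = "\t")), tsv)
  panel <- frequency_panel("toy_panel", path = tsv, subpops = "ALL")
  variants <- data.frame(chrom = "chrT", g_start = c(111L, 150L, 999L),
                         g_end = c(111L, 150L, 999L),
                         ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                         stringsAsFactors = FALSE)
  maf <- maf_summary(annotate_frequencies(variants, panel), panel)
  expect_setequal(maf$maf, c(1e-4, 0.4, 0))
  expect_true(all(maf$maf <= 0.5))
})

test_that("frequency printing matches the panel-output convention", {
  expect_equal(format_af(c(1e-4, 0.9999, 1, 0, 3e-4, 0.0013)),
               c("1.00E-04", "0.9999", "1", "0", "3.00E-04", "0.0013"))
})
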
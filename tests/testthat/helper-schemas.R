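# Documented output schemas, as written to CSV (quoted header lines).

conversion_header <- function() {
  paste0('"', c("Transcript_version", "Nucleotide_changes", "CDS_start_loc",
                "Ref", "Alt", "Chr", "ensembl_transcript_id", "hgnc_symbol",
                "start", "end", "width", "strand", "exon_id", "exon_rank",
                "tx_start", "tx_end", "refsnp_id", "genome_ref", "genome_alt",
                "note"), '"', collapse = ",")
}

annotation_header <- function(panel = "db_gnomAD_exome_freq") {
  pops <- c("ALL", "AFR", "AMR", "ASJ", "EAS", "FIN", "NFE", "SAS", "OTH")
  freq <- as.vector(rbind(sprintf("%s_%s_Ref_freq", panel, pops),
                          sprintf("%s_%s_Alt_freq", panel, pops)))
  paste0('"', c("Chr", "Start", "End", "Ref", "Alt", freq,
                "Func.knownGene", "Gene.knownGene", "ExonicFunc.knownGene",
                "AAChange.knownGene"), '"', collapse = ",")
}
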
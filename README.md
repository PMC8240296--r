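# txvar

Offline mapping of transcript-level single-nucleotide variants to
genomic coordinates, with coding-consequence calls, rsID lookup and
multi-population allele-frequency annotation.

## The problem

Patient variant lists are often written in transcript terms — a RefSeq
or UCSC accession and a CDS substitution such as `NM_005359` /
`A947G` — while dbSNP, gnomAD and 1000 Genomes are keyed by genomic
position and allele. Connecting the two means resolving the accession
to one transcript model, projecting the CDS position through the UTR
and the exon/intron structure onto the chromosome, and then joining
identifier and frequency databases. For a CDS position `p` on a model
with 5'UTR length `u` and exons `(s_i, e_i)` in transcript order:

```
t = p + u                               # transcript coordinate
k = min{ j : sum(w_1..w_j) >= t }       # containing exon, w_i = e_i - s_i + 1
g = s_k + (t - W_{k-1} - 1)             # plus strand (e_k - offset on minus)
codon = ceiling(p / 3),  frame = (p - 1) mod 3 + 1
```

txvar implements this chain for anyone — clinician, statistical
geneticist, pipeline author — who needs it reproducibly and without
network access: every database is a local file in an "annotation
bundle" (transcript GTF or refFlat, ID crossref TSV, genome FASTA,
dbSNP-style VCF, frequency-panel TSV/VCF), and a seeded synthetic
bundle generator makes the whole workflow testable with no downloads.

## Worked example

The package ships a small synthetic reconstruction of two human
GRCh37 transcript models (SMAD4 and BRCA2; exon scaffolds invented,
anchored quantities pinned to published annotation facts — see the
vignette). Converting three transcript variants:

```r
library(txvar)
d <- file.path(tempdir(), "demo"); demo_pdac_bundle(d, "grch37")
b <- load_bundle(d)
conv <- convert_transcript_id(file.path(d, "transcript_changes.csv"), b)
conv[, c("Transcript_version", "Nucleotide_changes", "Chr", "hgnc_symbol",
         "start", "exon_rank", "tx_start", "refsnp_id")]
```

```
 Transcript_version Nucleotide_changes Chr hgnc_symbol    start exon_rank tx_start   refsnp_id
          NM_005359              A947G  18       SMAD4 48586278         8     1485 rs377119288
          NM_000059             C3109T  13       BRCA2 32911601        11     3336  rs80358557
          NM_000059             A4599C  13       BRCA2 32913091        11     4826  rs80358694
```

Each row is one patient variant: the RefSeq accession resolved to an
Ensembl transcript, the CDS position projected to a 1-based genomic
coordinate (`start`), the exon holding it, the transcript coordinate
(`tx_start = CDS position + 5'UTR length`), and the rsID found in the
bundle's dbSNP file. Note the two `NM_000059` rows: the same
transcript with different CDS positions maps to two distinct genomic
variants.

The second command annotates genomic variants directly (it does not
require the conversion step). On the demo bundle's "compact" layout,
which includes a genome and a gnomAD-exome-style panel:

```r
dc <- file.path(tempdir(), "democ"); demo_pdac_bundle(dc, "compact")
bc <- load_bundle(dc)
pf <- pop_freq(file.path(dc, "variants.csv"), bundle = bc)
```

Written with `write_result_csv()` (selected columns):

```
"Chr","Start","Ref","Alt","...ALL_Ref_freq","...ALL_Alt_freq","Func.knownGene","ExonicFunc.knownGene","AAChange.knownGene"
"18",6278,"A","G","0.9999","1.00E-04","exonic","nonsynonymous SNV","SMAD4:uc002lfb.4:exon4:c.A482G:p.N161S,SMAD4:uc010xdp.2:exon8:c.A947G:p.N316S"
"13",11601,"C","T","1","0","exonic","stopgain","BRCA2:uc001uub.1:exon11:c.C3109T:p.Q1037X"
"13",13091,"A","C","0.9999","1.00E-04","exonic","nonsynonymous SNV","BRCA2:uc001uub.1:exon11:c.A4599C:p.K1533N"
```

Row 1 is a missense variant present in two SMAD4 isoforms (one
amino-acid-change entry per isoform); its alternate-allele frequency
in the panel is 1.00E-04, so the reference-allele frequency is the
complement 0.9999. Row 2 creates a premature stop (Q1037X, stopgain)
and is absent from the panel, which reports as `(1, 0)` — "not seen",
not "proven monomorphic". `maf_summary()` turns these rows into a tidy
per-subpopulation MAF table (and `plot_maf()` into bar charts).

A command-line front end wraps both commands:

```sh
Rscript inst/cli/txvar convert --input changes.csv --bundle demo/ --output out.csv
Rscript inst/cli/txvar popfreq --input variants.csv --bundle demo/ --panel db_gnomAD_exome_freq --output ann.csv
```

## Synthetic bundles

`generate_bundle(fixture_spec(seed = 42), dir)` writes a complete
bundle — genome, GTF, crossref, dbSNP VCF, frequency panel, input
CSVs — plus gold-standard expected outputs computed by independent
naive code, byte-identical for a fixed seed. These bundles are the
substrate of the test suite's exhaustive properties (per-base
roundtrip identity, oracle equivalence, protein-diff consequence
agreement).

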
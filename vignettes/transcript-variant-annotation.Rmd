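---
title: "Mapping transcript-level variants to the genome and annotating population frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcript-level variants to the genome and annotating population frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txvar)
```

## The problem

Clinical reports and older literature often describe a patient's
single-nucleotide variant in *transcript* terms — a RefSeq or UCSC
accession plus a CDS-relative substitution such as `NM_005359` /
`A947G` — while essentially every modern annotation resource (dbSNP,
gnomAD, 1000 Genomes) is keyed by *genomic* position and allele.
Bridging the two requires resolving the accession to a transcript
model, projecting the CDS position through the UTR offset and the
exon/intron structure onto the chromosome (with strand handled
exactly), and only then joining identifiers and allele frequencies.
txvar performs that whole chain offline, from a local "annotation
bundle" (GTF or refFlat transcript models, an ID cross-reference
table, a genome FASTA, a dbSNP-style VCF, and frequency-panel tables),
through two commands: `convert_transcript_id()` and `pop_freq()`.

## Coordinate systems and the projection model

Three 1-based coordinate systems are involved:

* **CDS position** `p`: base offset within the coding sequence, `p = 1`
  at the A of the start ATG.
* **Transcript position** `t`: base offset along the spliced mRNA from
  its 5' end, UTRs included, so `t = p + len(5'UTR)`, i.e.
  `t = cds_tx_start + p - 1`.
* **Genomic position** `g`: chromosome coordinate. Transcript base `t`
  falls in the exon whose cumulative-width interval contains `t`
  (cumulative widths in transcript order); within that exon
  `g = g_start + offset` on the plus strand and `g = g_end - offset` on
  the minus strand. On the minus strand, transcript base 1 is the
  genomically *rightmost* base of the rank-1 exon.

The containing exon is found by a cumulative-width search
(`findInterval`), which is `O(log n)` in the exon count. Because this
arithmetic is the one place a subtle off-by-one can silently corrupt
every downstream result, the package carries a deliberately naive
oracle, `per_base_map()`: plain concatenation of every exon's base run
(reversed per exon on the minus strand). The test suite and the
acceptance script compare the two representations at **every base of
every transcript** of a 100-transcript synthetic bundle and assert the
exhaustive roundtrip `genomic_to_transcript(transcript_to_genomic(t)) = t`.

Exon boundaries belong to their exon (closed intervals). Only width-1
substitutions are projected; insertions and deletions are out of scope
by design, matching the single-nucleotide definition of the input.

## Consequence calling

For a CDS substitution at `p`, the codon index and frame are pure
arithmetic: `codon = ceiling(p / 3)`, `frame = ((p - 1) mod 3) + 1`.
The reference codon is cut from the spliced CDS (exonic genome
sequence concatenated in transcript order, reverse-complemented on the
minus strand, then sliced to the CDS span); the alternate codon
substitutes one base. Both translate under the standard genetic code,
stop written as `X`. Classification:

| condition | class |
|---|---|
| ref aa = alt aa | synonymous SNV |
| alt aa = X | stopgain |
| ref aa = X ≠ alt aa | stoploss |
| codon 1, reference ATG disrupted | startloss |
| otherwise | nonsynonymous SNV |

Input alleles are interpreted in **transcript (coding-strand)
orientation**, because that is how CDS changes are written; the output
additionally reports the genome-plus-strand alleles (complemented on
minus-strand models), which are what position-keyed databases store.
When the genome base disagrees with the declared reference allele the
row is *flagged*, not dropped — patient tables routinely embed
annotation-version drift, and a flagged mapping is more useful than a
hole.

Genomic variants are region-classified per overlapping transcript:
`exonic` on a CDS base; `UTR5`/`UTR3` when exonic in a coding
transcript outside its CDS; `splicing` when intronic within 2 bp of an
exon boundary (the window is this package's documented choice — common
annotators use ±2 bp for the canonical splice dinucleotides);
`intronic` elsewhere in the span; `intergenic` when nothing overlaps.
Classes across transcripts combine by the priority exonic > UTR5 >
UTR3 > splicing > intronic. An exon hit on a *non-coding* transcript
reports `intronic` — the vocabulary has no ncRNA class, and claiming
`exonic` would imply a CDS that does not exist; this is a known
simplification. When several coding isoforms overlap a site, one
amino-acid-change entry per isoform is emitted (comma-joined, UCSC
accessions preferred for display when the crossref provides them) and
the most severe class is reported (stopgain > stoploss > startloss >
nonsynonymous > synonymous).

## ID resolution

Accessions resolve in three namespaces (RefSeq `NM_*`, UCSC `uc*`,
Ensembl `ENST*`). Exact versioned matches are preferred; otherwise
both sides are compared versionless — inputs are typically versionless
while crossref tables often carry versions. A RefSeq ID mapping to
several Ensembl transcripts is a real ambiguity with no published
disambiguation rule, so the package chooses determinism: rows flagged
canonical win, then the lexicographically smallest Ensembl ID; the
chosen mapping is logged. Non-coding transcripts load and resolve
normally but are rejected with a clear error by CDS-dependent
operations rather than silently dropped.

## Frequency panels

A panel is a named, ordered set of subpopulation codes plus a local
table (wide TSV with `AF_<POP>` columns, or VCF with per-population AF
INFO keys). The five built-in names follow the common public panels:
gnomAD exome/genome (ALL, AFR, AMR, ASJ, EAS, FIN, NFE, SAS, OTH),
1000 Genomes phase-3 continental populations (EAS, AMR, AFR, EUR,
SAS), and the two Taiwan Biobank extracts, which are single-population
(code ALL) because no subpopulation structure is published for them.

For a matching record, `Ref_freq = 1 - alt_freq` and
`Alt_freq = alt_freq` per subpopulation. A variant absent from the
panel — or a present record with an empty cell — reports `(1, 0)`.
This convention matches how such annotation tables are conventionally
printed, but **"absent from the panel" is not biologically the same as
"monomorphic reference"**; the output cannot distinguish the two, and
users comparing rare-disease cohorts against panels should keep that
in mind. Frequencies below 1e-3 print in scientific notation with two
decimals (`1.00E-04`); full precision is kept internally. MAF is
`min(Ref_freq, Alt_freq)`, so `(1, 0)` cells contribute MAF 0.

## Input table conventions

The variant CSV (`Chr,Start,End,Ref,Alt`) is 1-based with
`Start = End` for SNVs. BED input supports two dialects behind an
explicit flag because this is the classic silent off-by-one: under
`standard0` (true BED, 0-based half-open) Start is incremented on
read; under `table1` (the default) coordinates pass through, matching
the CSV convention that many published variant tables actually use
despite the `.bed` extension. Chromosome names are taken verbatim; an
explicit alias map (`apply_chrom_alias()`) is the only renaming
mechanism, because "chr18" vs "18" conventions differ between bundles
and guessing is worse than configuring.

## The synthetic bundle generator

`generate_bundle()` emulates the *structure* of real annotation data —
mixed strands, 1–6 exons, UTRs, spliced CDSs that start with ATG, end
with a stop, contain no internal stop and have length divisible by 3,
a position-sorted dbSNP-style VCF (with some multi-allelic records),
and a gnomAD-exome-shaped frequency panel with missing cells. It
deliberately does **not** emulate real gene-structure statistics
(exon-length distributions, GC content, isoform sharing, overlapping
genes): passing tests on these bundles demonstrates coordinate and
classification correctness, not robustness to every quirk of real
annotation releases. Each bundle ships gold tables (per-base maps,
expected conversion rows, expected consequences) computed by naive
single-pass code kept in the fixtures module and never called by the
production modules, so a shared bug cannot hide. Generation is
byte-identical for a fixed seed; at least five CAA→TAA stopgains are
planted per bundle. Default study conditions: 100 transcripts, half on
the minus strand, 30 planted variants, of which ~60% appear in the
panel.

A second, hand-built fixture (`demo_pdac_bundle()`) reconstructs two
human transcript models — SMAD4 (two isoforms) and BRCA2 on GRCh37 —
for the worked example. The exon scaffolds are synthetic, but the
quantities the example exercises are pinned to published annotation
facts: 5'UTR lengths of 538 and 227 nt, the exon ranks and IDs hosting
the example variants, the genomic anchors on chr18/chr13, and the
amino acids at the example codons. Within an anchored exon the
transcript-to-genome offset is constant, so the example mappings
(chr18:48,586,278; chr13:32,911,601; chr13:32,913,091; transcript
positions 1485/3336/4826) are exact, not approximations — the
surrounding scaffold affects nothing the example measures. The
"compact" layout shifts both loci near the origin and adds a small
invented genome realising the example codons (N316/N161, Q1037,
K1533), so the consequence and frequency paths run end to end without
multi-megabase FASTA files.

## Numerical and degenerate-input choices

* CDS lengths not divisible by 3 flag the model (`cds_incomplete`)
  rather than failing the load; consequence calls on a trailing
  partial codon translate to `?` and class `unknown`.
* Row-level failures in both commands (unknown ID, out-of-range CDS
  position, unparseable token) emit a diagnostic row and never abort
  the run; only bundle-configuration failures are fatal. Output order
  always equals input order.
* `tx_start = tx_end` is fixed for SNVs; `width` is always 1.
* Ties at exon boundaries cannot arise: exons are non-overlapping and
  closed, so every exonic base has exactly one containing exon.

## Validation scale

The shipped checks run, on one CPU in a few minutes: the exhaustive
per-base roundtrip and oracle comparison over a 100-transcript bundle
(~40,000 bases); all 1,080 substitutions of a 120-codon transcript
against the protein-diff oracle; frequency-complement and MAF
invariants over every emitted cell; and byte-identical regeneration of
a 12-transcript bundle. These sizes were chosen to make the property
sweeps exhaustive rather than sampled at the scale where exhaustion is
affordable.

## Limitations

* No indel/MNV/duplication grammar, no protein-level (`p.`) input, no
  liftover between assemblies, no NMD or splice-strength prediction,
  and only the standard genetic code.
* Published allele frequencies and rsIDs are database-version-pinned;
  the package reproduces whatever its local bundle files contain and
  makes no claim of matching any particular release.
* Region classification reports a single class per variant; borderline
  biology (e.g. an exonic base that is also 1 bp from a splice site in
  another isoform) is resolved by the fixed priority order, not by
  modelling.
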
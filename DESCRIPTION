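Package: txvar
Title: Transcript-Coordinate Variant Mapping and Population Allele
    Frequency Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps single-nucleotide changes given in transcript (CDS)
    coordinates onto genomic coordinates using local transcript models
    (GTF or refFlat), reports exon and transcript context, calls coding
    consequences (synonymous, missense, stopgain), looks up dbSNP-style
    rsIDs, and joins multi-population allele-frequency panels (gnomAD,
    1000 Genomes, Taiwan Biobank style). The whole workflow runs offline
    from a local annotation bundle; a seeded synthetic bundle generator
    makes every step testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    methods,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
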
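Package: irquant
Title: Intron Retention Quantification at Annotated Splice Junctions
Version: 0.1.0
Authors@R:
    person("Ana", "Ferreira", email = "ana.ferreira@example.org",
           role = c("aut", "cre"))
Description: Quantifies per-intron retention from split-read RNA-seq
    alignments at annotated exon-intron boundaries, with the gene-level
    stratifications used to study splicing during the Drosophila
    maternal-to-zygotic transition. Parses gene models from GTF, derives
    deduplicated splice boundaries with safety and length filters,
    classifies paired-end fragments at each 5' splice site as spliced,
    unspliced or mis-spliced, and summarises retention by gene class
    (maternal vs early-zygotic, from stage-expression thresholds) and
    intron-size bin. Also computes normalised read-coverage profiles
    around splice sites, 1000-segment exon-presence gene-structure
    profiles, splice-site position-frequency motif matrices, an in-silico
    RT-PCR amplicon-size calculator, and a seeded synthetic-data
    generator producing genome, annotation, expression table and
    alignments with known per-boundary retention truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
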
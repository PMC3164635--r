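Package: nemtrap
Title: Comparative Genomics and Trap-Formation Expression Analysis for a
    Nematode-Trapping Fungus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-implements, as a tested and reusable pipeline, the bespoke
    computations behind the comparative-genomic and expression analysis of
    the nematode-trapping fungus Arthrobotrys oligospora: sliding-window
    repeat-induced point mutation (RIP) index scanning and RIP-region
    calling over genome feature classes; reciprocal-best-hit orthology
    with four-way pathogen/non-pathogen gene categorization; single-linkage
    transitive-closure multigene family construction; concatenated
    single-copy-ortholog neighbor-joining phylogenomics; and 2^-ddCt qPCR
    and differential protein-spot quantification. A synthetic-data module
    generates every pipeline input with known ground truth (random genomes,
    RIP-mutagenized duplicated repeats, planted orthology hit tables,
    replicated Ct and spot-intensity tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    IRanges,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
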
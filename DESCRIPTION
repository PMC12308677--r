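Package: syytools
Title: Tandem tRNA Gene Cluster Decomposition, Repeat-Aware Bisulfite
    Methylation, and Ser/Tyr/Pro Proteome Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing tandem tRNA gene (tDNA) clusters of the
    SYY type found in the Arabidopsis thaliana nuclear genome: classification
    of annotated tDNA copies into dispersed/clustered localities, MAJOR/MINOR
    sequence families and exact intron variants; decomposition of a tandem
    cluster into ordered S-Y1-Y2 repeat units with positional composition and
    core/variable-region segmentation; construction of a degenerate consensus
    repeat reference (polymorphic columns masked to N, tDNA cassettes blocked
    to the MAJOR sequence) for repeat-aware bisulfite read mapping; strand-aware
    CG/CHG/CHH cytosine context classification, per-cytosine methylation
    calling, 20-bp binned methylation ratios, methylation-sensitive restriction
    site discovery and an in-silico chop-PCR digestion model; and proteome-wide
    Ser/Tyr/Pro composition with SP(n)Y tandem-motif detection and
    co-enrichment ranking. Includes seeded synthetic-data generators (clusters,
    methylomes, bisulfite reads, proteomes, and a genome-scale tDNA annotation
    deposit) with planted ground truth so every stage is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
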
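#!/usr/bin/env Rscript

# Step 1: generate the synthetic inputs for the whole workflow.
#   - a three-chromosome genome carrying a 27-unit tandem S-Y1-Y2 cluster
#     plus dispersed tRNA-Tyr/Ser copies, with its annotation table
#   - a full-scale 34-unit tandem SYY region
#   - a synthetic proteome with planted extensin-like repeat proteins
# Everything downstream reads only the files written here.

suppressPackageStartupMessages(library(syytools))

seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

d <- synthetic_tdna_deposit(seed = seed)
Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(unlist(d$genome)), "results/data/genome.fa")
write_tdna_table(d$annotations, "results/data/tdna_annotations.tsv")
write.table(
  data.frame(chrom = d$cluster_interval$chrom,
             start = d$cluster_interval$start,
             end = d$cluster_interval$end),
  "results/data/cluster_interval.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

region <- synthetic_syy_region(n_units = 34L, seed = seed)
write_cluster(region, "results/data/syy_region.fa",
              "results/data/syy_region.gff3", seqname = "syy_region")

prot <- generate_proteome(
  200, list(list(n_motifs = 12, n_prolines = 4, linker = ""),
            list(n_motifs = 10, n_prolines = 3, linker = "A")),
  seed = seed + 16L)
write_proteome(prot$proteins, "results/data/proteome.fa")

cat("wrote genome, annotations, SYY region and proteome under results/data\n")
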
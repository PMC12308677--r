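#!/usr/bin/env Rscript

# Step 4: consensus reference. Align the cluster's repeat units against the
# first unit, build the degenerate consensus (polymorphic columns -> N,
# Y1/Y2 cassettes blocked with the C-MAJOR sequence) and emit the edited
# genome in which the whole cluster is replaced by one consensus repeat.

suppressPackageStartupMessages(library(syytools))
dir.create("results", showWarnings = FALSE)

ann <- load_annotations("results/data/tdna_annotations.tsv",
                        "results/data/genome.fa")
ann <- assign_locality(ann)
fam <- classify_families(ann)

cl <- ann[ann$locality == "C", ]
cl <- cl[order(cl$start), ]
units <- assign_cassettes(
  decompose_repeats(cl[, c("id", "start", "end", "isotype")]),
  fam$gene_labels, genes = ann)

genome <- Biostrings::readDNAStringSet("results/data/genome.fa")
genome <- setNames(as.character(genome), sub("\\s.*$", "", names(genome)))
iv <- read.table("results/data/cluster_interval.tsv", header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
cluster_interval <- list(chrom = iv$chrom, start = iv$start, end = iv$end)

al <- align_units(genome[[cluster_interval$chrom]], units, ann)
tyr <- fam$classes[fam$classes$isotype == "Tyr", ]
major <- tyr$representative_sequence[tyr$locality == "C" &
                                       tyr$rank_label == "MAJOR"]
cons <- build_consensus(al, list(Y1 = major, Y2 = major))
ed <- emit_reference(as.list(genome), cluster_interval, cons,
                     annotations = ann)

Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(unlist(ed$genome)),
  "results/edited_reference.fa")
Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(c(consensus_repeat = cons$sequence)),
  "results/consensus_repeat.fa")
write.table(data.frame(n_position = cons$mask),
            "results/consensus_mask.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ed$annotations[, c("id", "chrom", "start", "end", "status")],
            "results/lifted_annotations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("consensus repeat: %d bp with %d N positions; genome shift %d\n",
            nchar(cons$sequence), length(cons$mask), ed$shift))
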
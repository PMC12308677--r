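#!/usr/bin/env Rscript

# Step 3: repeat structure of the cluster. Decompose the clustered genes
# into S-Y1-Y2 units, compute per-position MAJOR fractions, and segment the
# array into UVR / CR / CR* / DVR regions. Also decompose the full-scale
# 34-unit region from its GFF3.

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
seg <- segment_regions(units)

write.table(seg, "results/cluster_units.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(positional_composition(units), "results/positional_composition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# full-scale 34-unit region, read back from its GFF3
gff <- rtracklayer::import("results/data/syy_region.gff3")
genes <- gff[gff$type == "gene"]
rg <- data.frame(id = genes$ID,
                 start = GenomicRanges::start(genes) - 1L,
                 end = GenomicRanges::end(genes),
                 isotype = genes$isotype, stringsAsFactors = FALSE)
rg <- rg[order(rg$start), ]
runits <- decompose_repeats(rg)
write.table(runits[, c("index", "start", "end", "complete",
                       "s_id", "y1_id", "y2_id")],
            "results/syy_region_units.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cluster: %d units, CR of %d units; region: %d complete units\n",
            nrow(units), sum(seg$region_label == "CR"),
            sum(runits$complete)))
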
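#!/usr/bin/env Rscript

# Step 2: tDNA census. Load the annotations against the genome, assign
# clustered/dispersed locality, classify MAJOR/MINOR sequence families and
# intron variants, and scan the intron variants for the GCAGAT motif.

suppressPackageStartupMessages(library(syytools))
dir.create("results", showWarnings = FALSE)

ann <- load_annotations("results/data/tdna_annotations.tsv",
                        "results/data/genome.fa")
ann <- assign_locality(ann)
fam <- classify_families(ann)
iv <- cluster_intron_variants(ann[ann$isotype == "Tyr", ])

iv$variants$has_gcagat <-
  lengths(scan_motif(iv$variants$intron_sequence, "GCAGAT")) > 0

write.table(fam$classes, "results/tdna_families.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(iv$variants, "results/intron_variants.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(merge(merge(ann[, c("id", "chrom", "start", "end", "strand",
                                "isotype", "locality", "pseudogene_flag")],
                        fam$gene_labels, by = "id"),
                  iv$gene_labels, by = "id", all.x = TRUE),
            "results/tdna_catalog.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

tyr <- fam$classes[fam$classes$isotype == "Tyr", ]
cat(sprintf("Tyr copies: %d total, C-MAJOR %d, D-MAJOR %d\n",
            sum(tyr$copy_count),
            tyr$copy_count[tyr$locality == "C" & tyr$rank_label == "MAJOR"],
            tyr$copy_count[tyr$locality == "D" & tyr$rank_label == "MAJOR"]))
cat(sprintf("intron variants: %d clustered, %d dispersed\n",
            sum(iv$variants$locality == "C"),
            sum(iv$variants$locality == "D")))
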
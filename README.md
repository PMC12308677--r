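# syytools

Tools for analysing tandemly repeated tRNA gene (tDNA) clusters of the
*SYY* type — arrays whose repeat unit carries one tRNA-Ser and two tRNA-Tyr
cassettes (S–Y1–Y2), as found on *Arabidopsis thaliana* chromosome 1 —
together with the repeat-aware bisulfite-methylation and proteome-scanning
analyses that surround such a cluster.

The package covers five connected problems:

1. **tDNA catalog** — load and validate tDNA annotations against a genome,
   assign clustered (C) vs dispersed (D) locality, classify copies into
   exact-sequence MAJOR/MINOR families and intron variants (VAR1, VAR2, …),
   and scan introns for motifs such as `GCAGAT`.
2. **Cluster structure** — decompose the array into ordered S–Y1–Y2 repeat
   units, compute per-position MAJOR fractions, and segment the array into
   a core region (CR), a secondary core (CR\*), and upstream/downstream
   variable regions (UVR/DVR).
3. **Consensus reference** — align the units, build a single degenerate
   consensus repeat (polymorphic columns → `N`, Y1/Y2 cassettes *blocked*
   to the MAJOR sequence), and emit an edited genome in which the whole
   cluster is replaced by that one repeat, with coordinate liftover.
4. **Methylation** — strand-aware CG/CHG/CHH context classification,
   per-cytosine methylation calling from (simulated) bisulfite reads,
   20-bp binned call-weighted ratios, condition comparison,
   methylation-sensitive restriction (MSRE) site discovery (Bsp119I, MspI,
   HpyF3I) and an analytic in-silico chop-PCR digestion model.
5. **Proteome scan** — Ser/Tyr/Pro composition, extensin-like `SP(n)Y`
   tandem-motif detection, and Ser/Tyr co-enrichment ranking.

Every module has a seeded synthetic-data generator with planted ground
truth (clusters, methylomes, bisulfite reads, proteomes, and a
genome-scale tDNA annotation deposit), so the full pipeline runs and is
tested entirely offline. All sequences in the deposits are invented; only
their *class structure* mirrors the census of the endogenous cluster.

## Worked example

Census of a synthetic tDNA deposit, decomposition, consensus, methylation
and proteome ranking — the printed values below are the actual outputs:

```r
library(syytools)

d   <- synthetic_tdna_deposit(seed = 1)
ann <- assign_locality(load_annotations(d$annotations, d$genome))
fam <- classify_families(ann)
tyr <- fam$classes[fam$classes$isotype == "Tyr", ]
sum(tyr$copy_count)
#> [1] 70
tyr$copy_count[tyr$locality == "C" & tyr$rank_label == "MAJOR"]
#> [1] 32
tyr$copy_count[tyr$locality == "D" & tyr$rank_label == "MAJOR"]
#> [1] 14

iv <- cluster_intron_variants(ann[ann$isotype == "Tyr", ])
table(iv$variants$locality)
#>  C  D
#>  7 12
# GCAGAT is present in all clustered intron variants except one (truncated)
sum(lengths(scan_motif(
  iv$variants$intron_sequence[iv$variants$locality == "C"], "GCAGAT")) == 0)
#> [1] 1

# repeat decomposition + segmentation of the clustered array
cl <- ann[ann$locality == "C", ]; cl <- cl[order(cl$start), ]
units <- assign_cassettes(
  decompose_repeats(cl[, c("id", "start", "end", "isotype")]),
  fam$gene_labels, genes = ann)
nrow(units)
#> [1] 27
positional_composition(units)$fraction_major
#> [1] 0.3703704 0.8148148        # Y1, Y2
sum(segment_regions(units)$region_label == "CR")
#> [1] 10

# degenerate consensus repeat, Y1/Y2 blocked with the C-MAJOR sequence
major <- tyr$representative_sequence[tyr$locality == "C" &
                                       tyr$rank_label == "MAJOR"]
cons <- build_consensus(align_units(d$genome$Chr1, units, ann),
                        list(Y1 = major, Y2 = major))
c(nchar(cons$sequence), length(cons$mask))
#> [1] 441  10

# methylation recovery at 200x simulated coverage (planted 0.8/0.4/0.05)
ref <- withr::with_seed(12, random_dna(3000))
mt  <- generate_methylome(ref, c(CG = 0.8, CHG = 0.4, CHH = 0.05))
tr  <- call_methylome(
  generate_bisulfite_reads(ref, mt, 200, 100, seed = 13)$reads, ref)
sapply(c("CG", "CHG", "CHH"), function(ctx) {
  s <- tr$context == ctx; sum(tr$meth[s]) / sum(tr$total[s])
})
#>        CG       CHG       CHH
#> 0.7971872 0.3952144 0.0504195

# chop-PCR: amplifiable fraction with one CG site 80% methylated
simulate_chop_pcr(0.8, delta = 1, n_molecules = 1e5, seed = 7)
#> $analytic
#> [1] 0.8
#> $monte_carlo
#> [1] 0.79882

# proteome: planted extensin-like repeat proteins surface at the top
prot <- generate_proteome(200, list(
  list(n_motifs = 12, n_prolines = 4, linker = ""),
  list(n_motifs = 10, n_prolines = 3, linker = "A")), seed = 17)
head(rank_coenrichment(prot$proteins)[, c("id", "pct_S", "pct_Y",
                                          "n_motifs", "motif_coverage")], 2)
#>      id    pct_S    pct_Y n_motifs motif_coverage
#> 1 rep02 16.94915 16.94915       10      0.8474576
#> 2 rep01 16.66667 16.66667       12      1.0000000
```

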
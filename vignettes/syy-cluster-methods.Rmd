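---
title: "Methods: modelling a tandem tRNA gene cluster, its consensus reference, methylation and proteome signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling a tandem tRNA gene cluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(syytools)
```

This vignette documents the models, conventions and numerical choices behind
`syytools`. The package implements the computational core of an analysis of a
tandemly repeated tRNA gene cluster (the *SYY cluster*: repeat units each
carrying one tRNA-Ser and two tRNA-Tyr cassettes, S–Y1–Y2), together with the
bisulfite-methylation and proteome-scanning machinery used around such a
cluster. Because the original genome annotations are not bundled, every
module comes with a synthetic data generator whose *class structure* mirrors
the census of the endogenous locus while all sequences are invented; the
analysis pipeline
itself never looks at the generators' ground truth.

## Coordinate and sequence conventions

All internal coordinates are 0-based, half-open `[start, end)`, on explicit
`+`/`-` strands; GFF3 output converts to 1-based inclusive coordinates at the
boundary. Sequence classes (gene families, intron variants) are *exact
string* equivalence classes — no alignment or similarity threshold is
involved, which keeps classification deterministic and order-free.

## The tDNA catalog (`load_annotations`, `classify_families`)

`load_annotations()` validates an annotation table against a genome
(bounds, intron nesting) and extracts strand-aware mature and intron
sequences. Locality is assigned by `assign_locality()` either from explicit
cluster intervals (overlap rule) or by a pairwise-gap rule: genes closer
than `distance` (default 2000 bp, roughly one repeat-unit length scale) on
the same chromosome coalesce into clusters; every multi-gene cluster is
"C", the rest "D".

Within each (isotype, locality) group, `classify_families()` ranks exact
mature-sequence classes by descending copy number — the largest is MAJOR,
the rest MINOR1, MINOR2, ... with ties broken by the genomic position of
each class's first member so that labels are reproducible. Intron variants
(`cluster_intron_variants()`) follow the same convention per locality
(VAR1, VAR2, ...); truncated introns are distinct variants, and intronless
copies are ignored rather than forming a pseudo-variant.

## Repeat decomposition and segmentation (`decompose_repeats`, `segment_regions`)

`decompose_repeats()` walks cassettes in genomic order and greedily groups
each Ser cassette with the next two Tyr cassettes into an S–Y1–Y2 unit;
cassettes that break the grammar are reported as anomalies instead of being
forced into units. Unit intervals are widened to the midpoints between
adjacent units so the array is tiled without gaps; trailing partial units
are kept but flagged `complete = FALSE` and excluded from composition
statistics.

`segment_regions()` segments the array into a core region (CR) and
upstream/downstream variable regions (UVR/DVR). A unit qualifies when the
fraction of MAJOR Y1/Y2 pairs in a *centered* window of `w` units (default
3) reaches `tau` (default 2/3). Centered windows were chosen over trailing
windows because they recover a planted core exactly at the default
parameters instead of absorbing one flanking unit on each side. The longest
run of qualifying units is the CR; a second, disjoint downstream run is
labelled CR*; units before the CR are UVR, units after the last core are
DVR, and interior non-qualifying units stay `unassigned`.

## Consensus reference (`align_units`, `build_consensus`, `emit_reference`)

The consensus module builds the single degenerate repeat that replaces the
whole cluster in an edited reference. Units are cut into seven segments
(flanking/inter-cassette spacers and the three cassettes) and each segment
is aligned against the *first* unit as anchor — a deliberate simplification
that is exact for arrays born by tandem duplication (segments of equal
length take an identity shortcut; unequal segments go through
`Biostrings::pairwiseAlignment`). Columns present in fewer than half the
units (insertions relative to the anchor) are dropped, with a warning when
they are widespread.

Column rules: a column with two or more distinct residues becomes `N`; the
`mask` records those positions. Cassette columns for the Y1/Y2 roles can be
*blocked*: they are forced to the supplied MAJOR mature sequence
byte-for-byte and never contain `N`. Introns are intentionally *not*
blocked — intron variation is biologically informative and must survive in
the consensus — so `build_consensus()` also reports the consensus intron
intervals (i1 in Y1, i2 in Y2). `emit_reference()` splices the consensus
repeat over the cluster interval, recomputes downstream coordinates, and
returns a lift function (identity upstream, shifted downstream, `NA`
inside the replaced interval); annotations inside the interval are flagged
`collapsed`.

## Methylation (`classify_context`, `call_methylome`, `bin_methylation`, `simulate_chop_pcr`)

Contexts follow the plant convention, strand-aware and downstream of the
cytosine: CG, CHG, CHH with H ∈ {A, C, T}; a needed base that is `N` or
beyond the sequence end yields `ambiguous`. The caller runs in
truth-placement mode (simulated reads carry their origin), counting read C
as methylated and read T as unmethylated at reference cytosines of the
read's strand; other bases are treated as sequencing errors and ignored.
`place_reads()` provides a naive exact-match placement (bisulfite-aware,
`N`-tolerant) for small end-to-end runs — it is not an aligner.

`bin_methylation()` tiles a feature with fixed 20-bp bins (the last bin may
be partial) anchored at the feature's 5′ end and reports a *call-weighted*
ratio per (bin, context), pooling strands: `sum(meth) / sum(total)`. This
makes pooled per-context values recoverable from bins by call-weighted
averaging, which the tests assert as an invariant.
`compare_conditions()` is purely descriptive (deltas, no tests).

The planted methylome is deterministic: every unambiguous cytosine receives
its context level exactly, so the per-context mean of planted probabilities
equals the level, and estimator bias can be measured without
generator noise. Read simulation draws uniform starts and strands;
per-cytosine states are Bernoulli draws from the planted probability,
followed by optional conversion failure and substitution error.

The chop-PCR model treats an amplicon as uncut only if every diagnostic
MSRE site survives: site *i* with methylation fraction `m_i` is cut with
probability `(1 - m_i) * delta`, independently, giving the analytic
amplifiable fraction `prod(1 - (1 - m_i) * delta)`; the mock control is 1
by definition. A Monte-Carlo mode exists solely to validate the analytic
expression. The bundled enzymes are Bsp119I (TTCGAA, CG probe), MspI
(CCGG, CHG probe at the outer C) and HpyF3I (CTNAG, CHH probe); the
diagnostic cytosine's context is always computed from the actual sequence,
so e.g. a CTGAG site is a CHG probe, not CHH.

## Proteome scan (`find_spny_motifs`, `rank_coenrichment`)

The extensin-like motif grammar is `S P{n} Y` with `n_min <= n <= n_max`
(default `n >= 2`), matched maximally and non-overlapping, left to right —
there is no standard grammar for these repeats, so this explicit choice is
recorded here and enforced against an independent state-walk oracle in the
tests. Composition percentages use the 20 standard residues as the
denominator (X excluded). The co-enrichment score is the geometric mean of
the within-proteome percentile ranks of %S and %Y; %P and motif coverage
are carried as annotations rather than entering the score, and ties are
broken by id so rankings are order-invariant.

## Synthetic deposits

`synthetic_tdna_deposit()` builds a three-chromosome genome whose planted
class structure reproduces the census the pipeline is expected to recover:
70 Tyr copies; a 27-unit clustered array carrying 54 clustered Tyr copies
(32 C-MAJOR + 9 minor classes totalling 22, of which 13 copies are
pseudogene-flagged "tRNA-like"); 16 dispersed Tyr copies (14 D-MAJOR + 2
minors); 7 clustered and 12 dispersed intron variants with the GCAGAT motif
in all clustered variants except the truncated one. The array is generated
as a true tandem duplication (shared spacer templates), so the consensus
step sees realistic homogeneity: the planted intron substitutions are the
only polymorphic columns. `synthetic_syy_region()` generates a separate
34-unit region at the endogenous repeat scale used for decomposition-only
analyses. The 27-unit/34-unit split reflects that the copy census and the
repeat-unit count are modelled as two different fixtures rather than forced
into one genome. Problem sizes (40–60 kb chromosomes, 200-protein
proteomes, 200× coverage) are the package's own choices, balancing runtime
against estimator precision.

## Worked example

```{r census}
d <- synthetic_tdna_deposit(seed = 1)
ann <- assign_locality(load_annotations(d$annotations, d$genome))
fam <- classify_families(ann)
tyr <- fam$classes[fam$classes$isotype == "Tyr", ]
tyr[, c("locality", "rank_label", "copy_count")]
```

```{r consensus}
cl <- ann[ann$locality == "C", ]
cl <- cl[order(cl$start), ]
units <- assign_cassettes(
  decompose_repeats(cl[, c("id", "start", "end", "isotype")]),
  fam$gene_labels, genes = ann)
major <- tyr$representative_sequence[tyr$locality == "C" &
                                       tyr$rank_label == "MAJOR"]
cons <- build_consensus(align_units(d$genome$Chr1, units, ann),
                        list(Y1 = major, Y2 = major))
c(length_bp = nchar(cons$sequence), n_positions = length(cons$mask))
```

```{r methylation}
ref <- withr::with_seed(11, random_dna(2000))
mt <- generate_methylome(ref, c(CG = 0.8, CHG = 0.4, CHH = 0.05))
rs <- generate_bisulfite_reads(ref, mt, coverage = 100, read_length = 100,
                               seed = 12)
tr <- call_methylome(rs$reads, ref)
sapply(c("CG", "CHG", "CHH"), function(ctx) {
  sel <- tr$context == ctx
  sum(tr$meth[sel]) / sum(tr$total[sel])
})
```

## Limitations

* The aligner anchors on the first unit and drops insertions relative to
  it; arrays with long unit-specific insertions are outside the model.
* `place_reads()` is exhaustive exact matching, quadratic in practice;
  real data needs a real bisulfite aligner.
* The chop-PCR model ignores PCR efficiency, primer effects and partial
  digestion heterogeneity beyond the single `delta` parameter.
* The methylome model is i.i.d. per cytosine within context — no spatial
  autocorrelation, no per-copy epiallele structure.
* All census-scale claims are about the synthetic deposits; the package
  ships no real genome data.
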
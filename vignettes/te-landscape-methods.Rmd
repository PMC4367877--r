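---
title: "Methods: TE landscape analyses and their assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE landscape analyses and their assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`telandscape` computes, from an annotated genome and a repeat-hit file,
seven related summaries of the genomic landscape of transposable element
(TE) copies: location tracks, per-chromosome occurrence curves, a
genome-wide family frequency table, copy-size histograms, genome coverage
proportions, a TE–gene proximity classification with its derived distance
histograms and Gene Ontology (GO) distributions, and a master TE–gene
feature table. This vignette describes the model behind each summary, the
parameters that matter, the synthetic-data generator used for testing,
and the numerical and design choices a careful reader will want to know.

## Coordinate model

Every interval is 1-based and inclusive on both ends, the convention of
GenBank, EMBL and RepeatMasker output; a region `[start, end]` covers
`end − start + 1` bases. Input parsers translate each dialect at the
boundary only, and BED export converts to 0-based half-open coordinates
at the boundary in the other direction. The *gap* between two features is
the number of bases strictly between them: overlapping or bookended
features have gap 0. The distance between a TE copy and a gene is
edge-to-edge (closest edges), not midpoint-to-midpoint; the choice is a
package decision — midpoints would make the proximal threshold depend on
feature lengths, which is hard to defend for kilobase-scale genes.

## Inputs

* **Annotation** — GenBank or EMBL flat files, or a native 7-column TSV
  (`chrom, start, end, strand, kind, gene_name, gene_numeric_id`; rows of
  kind `chromosome` declare chromosome lengths, `#!organism` declares the
  organism). Feature kinds form a closed set: gene, exon, pseudogene,
  miscRNA, five_prime_UTR, three_prime_UTR. A gene's span is its
  outermost annotated coordinates, so introns and internal UTRs count as
  gene body; `join(...)` locations flatten to the enclosing span with
  each segment additionally emitted as an exon. Genes carry an NCBI
  numeric GeneID when a `/db_xref="GeneID:n"` qualifier is present; genes
  without one are skipped by GO lookups and surface in the explicit
  `unannotated` bucket rather than disappearing.
* **Repeat hits** — RepeatMasker `.out`, Censor map, NCBI-BLAST tabular
  (outfmt 6), AB-BLAST tabular, Repet tabular, or a native 7-column TSV.
  All are normalised to one copy table with percent similarity to the
  family consensus: RepeatMasker's divergence becomes `100 − div`;
  Censor's fractional similarity is scaled by 100; BLAST percent identity
  is used directly. Hits are never merged or defragmented — a fragmented
  copy is reported as often as the detector reported it, which keeps
  sub-300 bp fragments visible in size histograms. The AB-BLAST and Repet
  column maps are explicit package definitions (documented in
  `?repeat_io`); unrecognisable lines fail loudly with a line number
  rather than being guessed at.
* **Ontology** — NCBI `gene2go` (optionally taxon-filtered, no
  evidence-code filtering) and a GO graph in OBO 1.2. Slim vocabularies
  are either level-based (`TreeLevel1` = children of the namespace roots,
  `TreeLevel2` = their children, the two levels kept disjoint), a custom
  id list, or the packaged `goslim_generic_synthetic.txt` — a synthetic
  stand-in for the EBI generic slim made of broad, real GO accessions;
  for faithful work against the current EBI list, supply that list as a
  file.

## The proximity classification

Each selected copy is assigned exactly one of four categories, in
precedence order:

1. **ExonIntronUTR** — the copy overlaps a gene or pseudogene body by at
   least one base, regardless of flank distances.
2. **ProximalPromoter** / **Proximal3End** — otherwise, among the two
   flank genes with gap ≤ *D* (default **3,000 bp**, threshold
   *inclusive*: a copy at exactly 3,000 bp is proximal, at 3,001 bp it is
   not), the gene with the smaller gap decides; the copy is promoter-
   proximal if it lies on that gene's 5′ side after applying the gene's
   strand, 3′-proximal otherwise. Unstranded genes are treated as
   forward. When both flank genes are *exactly* equidistant, the
   promoter interpretation wins — a documented tie-break, chosen because
   promoter proximity is the biologically loaded call.
3. **Intergenic** — no gene within *D* on either side.

"Left/right" neighbors are purely coordinate-based and reported as such
in the feature table (`relation` column: left/right/within), while the
category column is strand-aware; keeping the two senses separate avoids
the ambiguity of "upstream" meaning either smaller coordinate or 5′.
Neighbor searches consider `gene` and `pseudogene` features only
(configurable via `proximity_config(neighbor_kinds = )`); exons and UTRs
are parts of genes, not neighbors. Promoter proximity is measured from
the gene-span boundary, not an annotated TSS.

## Panel computations

* **Occurrence curves** (`chromosome_distribution()`): the chromosome is
  split into `n_bins` equal-width bins (the integer-division remainder
  goes to the last bin) and each copy is counted once, in the bin holding
  its midpoint — a copy straddling an edge is never double-counted. The
  bin count is a free display parameter (CLI default 100).
* **Genome frequency** (`genome_frequency()`): for each family the
  per-chromosome percentage is that chromosome's share of the *family's
  own* genome-wide copies, so each family's percentages sum to 100; the
  chromosome length shares of the genome are reported alongside. The
  per-family normalisation is the only reading consistent with a family
  being "overrepresented" on a chromosome relative to that chromosome's
  length share.
* **Size histograms** (`size_histogram()`, default 40 intervals):
  equal-width bins over `[size_min, size_max]` (defaults: observed
  bounds), left-closed with a right-closed last bin; out-of-range copies
  are excluded, not clamped.
* **Coverage proportions** (`size_proportions()`): per item class, the
  union of its intervals (each base counted once, overlapping members
  collapsed via `IRanges::reduce`) as a percent of total genome length.
  Classes overlap freely — genes and exons double-cover — so the
  percentages deliberately do not sum to 100.
* **Region distance histograms** (`region_position_histogram()`, default
  20 intervals): gap distances of one proximal category binned over
  `[0, D]`, bin 0 nearest the gene boundary. The two non-proximal
  categories have no distance axis and are rejected.
* **GO distributions** (`neighbor_go_distribution()`): each copy
  contributes its flank neighbors and any containing genes; each gene
  instance contributes its *set* of slim-projected terms (a gene
  annotated to three descendants of one slim term counts that term once
  per instance, so annotation redundancy cannot inflate slices).
  Proportions are per slim-term assignment and sum to 1 including the
  `unannotated` bucket. The 1% display threshold pools small slices into
  "other" in plots only; tables stay itemised.
* **Feature table** (`build_feature_table()`): at least two rows per copy
  (left and right neighbor) plus one per containing gene; a copy on a
  gene-free chromosome keeps a placeholder row (`relation = "none"`) so
  copy counts remain auditable. The `ortholog_X` column counts the
  organisms in which the (family, gene, relation) couple occurs, genes
  matched case-insensitively by name or through an optional ortholog-map
  file — the orthology criterion is name identity by default because
  nothing stronger can be inferred from annotation alone.

## The synthetic-data generator

`simulate_te_genome()` writes a complete input set (GenBank, EMBL and
native annotation; RepeatMasker and native repeat files; toy gene2go,
OBO graph, slim list and superfamily table) with planted ground truth.
Defaults describe the standard test genome: 2 chromosomes × 2 Mb, 100
genes per chromosome of 1–3 kb, 5% of them pseudogenes, three
Helitron-like families of 200 copies each (150–1,200 bp, 55–100%
similarity), and planted category proportions 0.10 within / 0.25
promoter / 0.25 3′ / 0.40 intergenic.

Placement is *constructive*, not rejection-sampled: genes are spaced at
least `2(D + max copy size) + margin` apart, so every flank zone is
unambiguous; a proximal copy is placed at a gap drawn uniformly from
`[0, D]` on the intended side of the intended gene, which is then
provably its nearest gene; intergenic copies are placed farther than
`D + max copy size` from every gene. Planted proportions are therefore
recovered *exactly* by the classifier, and tests need no tolerance.
Similarities are drawn to one decimal so the RepeatMasker divergence
column (one decimal) round-trips exactly. Each content kind (gene
layout, TE placement, GO assignment) uses its own seed-derived random
stream, so a given seed yields byte-identical files run-to-run.

What the generator does *not* emulate — and what passing tests therefore
do not show: nucleotide sequence (coordinates only), nested or
fragmented TE copies, overlapping genes, real gene-density gradients
(centromeres), or real GO annotation structure. The closure tests prove
the analysis engine is exact on well-separated features; on real
genomes, overlapping genes and TE nesting exercise the documented
precedence rules instead.

## Numerical choices and degenerate inputs

Filter bounds are inclusive at both ends (a 49.9%-similar copy fails the
default 50% floor; a copy at exactly 50.0% passes). Size filter bounds
default to the observed minimum and maximum of the copies being
filtered. Empty inputs are legal everywhere: empty repeat sets give
all-zero histograms, zero-row category tables and header-only BED files
rather than errors; division by zero is avoided by reporting `NA`
percentages for families with zero copies. Proportion sums are exact to
1e-9 in tests. Neighbor ties on identical gap are broken toward the
gene with the smaller start coordinate; the promoter-wins rule above
applies only to the left-vs-right tie.

## Test and fixture sizes

The test suite validates the interval, slim-projection and neighbor
operations against independent brute-force oracles (base-marking arrays,
exhaustive scans, graph reachability) on hundreds of random instances,
checks conservation laws (bin sums, 100% family sums, unit proportion
sums) across twenty fixture seeds, and runs the full pipeline closure on
the standard 2 × 2 Mb genome; these sizes give sub-minute runs while
exercising every branch. `scripts/acceptance.R` re-runs the closure and
oracle suite from scratch on a seed given at the command line.

## Known limitations

GFF3/GTF input is not supported (the annotation dialects are the flat
files plus the native TSV). No statistical testing is attached to GO
distributions — they are descriptive proportions, not enrichment tests.
Exonic and intronic insertions are not distinguished (a single
within-gene category). RepeatMasker-style fragment defragmentation is
out of scope by design: counts are per reported hit, not per inferred
element.
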
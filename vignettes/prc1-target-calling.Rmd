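---
title: "Calling PRC1 co-occupancy sites and classifying candidate target genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling PRC1 co-occupancy sites and classifying candidate target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prc1targets)
```

## The problem and the model

Mammalian PRC1 is not one complex but a family: a canonical assembly draws
one subunit each from the Pc (CBX), Psc, Ph and Sce (RING) ortholog
families. When several orthologs are profiled by ChIP-seq in the same
cells, the question is whether they occupy distinct target genes or
congregate at common sites. The analysis implemented here takes the
congregation view operationally: a genomic region is a *candidate PRC1
target site* when at least one CBX protein, at least one RING protein and
the PRC2 mark H3K27me3 are all detected there. Requiring a RING protein
captures every catalytically active PRC1 (each contains RING1 or RING2);
requiring a CBX protein restricts to canonical, chromobox-containing
complexes; requiring H3K27me3 anchors the site in Polycomb chromatin.

The pipeline then treats the *gene*, not the peak, as the unit of
interpretation. Sites are attached to the gene with the nearest TSS, and
the per-gene constellation of sites is summarised as a peak-architecture
category. This matters because PRC1 peaks are frequently not single
promoter-proximal blocks: a substantial minority sit closest to the 3' end
of the transcription unit, many loci carry peaks at both ends or across
the body, and distances from the TSS can reach hundreds of kilobases.

Assumptions worth stating explicitly:

* Peak calls are trusted as given (MACS-style narrowPeak or BED); the
  package performs no signal-level re-analysis.
* Overlap of binding regions is evidence of co-binding. Sub-peak-resolution
  colocalization (e.g. sequential ChIP) is outside what peak data can show.
* One merged span per linked cluster of peaks is an adequate unit: the
  criterion is evaluated per span, not per base.
* Activity can be read from raw counts in duplicate RNA-seq libraries with
  a fixed threshold; no normalization or differential testing is implied.

## Coordinate conventions

Peak and annotation files follow their native conventions — BED-family
files are 0-based half-open, GTF is 1-based inclusive. Internally
everything is a `GRanges` (1-based, closed), the native Bioconductor
convention, with conversion confined to the I/O boundary. This buys every
interval operation (merging, overlap, coverage) from IRanges rather than
re-deriving it, at the cost of a ±1 shift when comparing raw file values
with in-memory objects; the readers and writers are round-trip tested in
both directions.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| replicate mode | union | — | replicate merging is used to improve the definition of sites, not to demand reproducibility in both libraries; `intersection` (bases covered by ≥2 replicates) is available |
| `merge_gap` | 0 | bp | within-factor merging joins only overlapping/abutting peaks |
| `link_gap` | 1000 | bp | how far apart different antibodies' peaks may sit and still count as one binding event; 1 kb spans summit scatter without bridging distinct loci |
| `required_mark` | H3K27me3 | — | the compilation criterion |
| `foothill_min_fraction` | 0 | fraction of site max score | foothill peaks (weak flanking contacts) are *kept* by default and interpreted, not filtered; the filter exists for sensitivity analyses and flags (rather than drops) sites that stop satisfying the criterion |
| `end_window` | 10 000 | bp | the conventional promoter-proximal range in this kind of analysis; kept configurable because real distances reach far beyond it |
| `body_overlap_fraction` | 0.5 | fraction of site span | a site half inside the body is "internal enough" to defeat the flanking-only subcategory |
| `max_assignment_distance` | unbounded | bp | distant sites are genuinely assignable (single-neighbour cases); the signed distance is always reported so users can filter |
| reference point | midpoint | — | co-occupancy sites aggregate many antibodies' peaks, so no single summit is privileged |
| `activity_threshold` | 10 | reads | "ten reads in duplicate samples", read as ≥10 in *each* replicate; the sum-based reading is available as `mode = "sum"` |
| `h3k4me3_window` | ±2000 | bp | the conventional promoter window; the association window is not otherwise determined |

Factor classes (CBX / RING / HISTONE\_MARK / OTHER) are configuration, not
code: the registry is a two-column table, so additional PRC1 components
(HPH, BMI1, MEL18, ...) can be added without touching the package.

## Assignment and classification rules

Nearest-TSS ties are broken deterministically: prefer the coding gene,
then the lexicographically smallest gene id. This extends the coding-gene
preference to the zero-measure tie case so that reruns are identical.

Two exceptions modify pure nearest-TSS assignment. A site overlapping both
a coding and a noncoding gene body is assigned to the coding gene
(nearest-TSS among the overlapped coding genes). A site overlapping the
bodies of two or more *closely linked* genes — operationalized as bodies
within `2 * end_window` of each other — makes those genes `AMBIGUOUS`:
the peaks cannot be attributed to a specific locus. Genes already resolved
by the coding preference do not participate in ambiguity. The ambiguous
site is owned, for bookkeeping, by its nearest-TSS gene, but every
involved gene receives an `AMBIGUOUS` call referencing it; ambiguous calls
carry `NA` distances and are excluded from category proportions (and
counted separately).

Classification uses the minimum distance from any assigned site midpoint
to the TSS and TES. Clusters within `end_window` of both ends give
`BOTH_ENDS`; a TES-side cluster only — or, with no cluster at all, a
strictly nearer TES — gives `TES_ASSOCIATED`; everything else is
`TSS_ASSOCIATED`. For genes shorter than `2 * end_window` the window
shrinks to half the gene length (logged and flagged per call), since
otherwise the two end windows overlap and every site would belong to both
clusters; for such short genes the TSS/TES distinction is admittedly
debatable.

One rule interaction is worth recording: the `INTERNAL` subcategory of
`BOTH_ENDS` ("all sites inside the body, none near either end") cannot
co-occur with the cluster-based definition of `BOTH_ENDS` itself, which
requires sites near both ends. The subcategory is retained in the schema
for completeness, but under the default rule only `FLANKING_DISCRETE` and
`DISTRIBUTED` are reachable, and the generator plants only those two.

The spacing-regularity score for peak arrays is `max(0, 1 − CV)` of
successive summit gaps (at least four peaks). It is a summary statistic
that flags evenly spaced arrays; it is not a periodicity test and carries
no significance claim.

## What the generator emulates — and what it does not

`generate_dataset()` plants target loci on three synthetic chromosomes and
realizes them as narrowPeak files with the study's structure: five PRC1
factors × two replicates × two strains, H3K27me3 domains over each planted
cluster, H3K4me3 at flagged and active promoters, duplicate
negative-binomial count tables, and a senescent condition that is the
second strain with all scores multiplied by `senescence_scale` at
unchanged locations.

Defaults are the study conditions: category mix 0.66/0.155/0.18
(TSS/TES/both-ends, remainder ambiguous pairs), a 685:301:414-proportioned
shared/strain-specific split, 28% active targets against a 47%
genome-wide active rate, 38% of targets flagged with promoter H3K4me3, and
senescence scale 0.6. Noise: per-replicate summit jitter N(0, 50 bp) and
gamma-distributed scores with CV 0.2 around per-locus, per-factor means —
values chosen once so that default recovery is near-perfect while stress
configurations remain a parameter away. Counts use a negative binomial
(dispersion 0.1; silent mean 1, active mean 100), chosen only to respect
the threshold semantics, not to mimic real library depth; label
consistency (active ⇒ ≥ threshold in every replicate, silent ⇒ below it in
at least one) is enforced after drawing.

Geometry is chosen so that planted labels are recoverable by construction:
genes occupy one 100 kb slot each (ambiguous pairs share a region, 4 kb
apart), planted clusters keep ≥20% margin from `end_window` boundaries,
and inter-gene gaps exceed the worst-case own-TSS distance of a planted
TES-proximal site, so nearest-TSS assignment cannot leak onto a
neighbour. The genome therefore scales with `n_genes` (~100 kb per gene)
rather than being fixed: recoverability under the default 10 kb window
sets a minimum per-gene footprint. Decoy loci carrying incomplete factor
combinations (CBX only, RING only, CBX+RING without the mark, mark only)
are planted among non-targets so that specificity is tested against
non-trivial negatives.

What the generator does *not* model — and what passing tests therefore do
not show about real data: irregular gene density and overlapping
transcription units (real assignment ambiguity is far more common),
antibody-specific efficiency differences, peak-caller artefacts,
copy-number or mappability biases, and any sequence content. Recovery
rates on this landscape are a correctness check of the pipeline's logic,
not an estimate of its accuracy on real chromatin.

## Senescence comparison

The proliferating/senescent comparison is deliberately descriptive:
reciprocal location overlap plus a median matched-site score ratio. A
preserved landscape at globally reduced read density appears as overlap
near 1 with a ratio below 1. No significance test is attached, matching
the qualitative nature of the claim; differential-binding statistics are
out of scope.

## Numerical and degenerate-input choices

* Merging with gap *g* joins intervals separated by ≤ *g* bases
  (`reduce(min.gapwidth = g + 1)`); intersection mode is defined per base
  (coverage ≥ 2 of per-replicate unions) and is verified against a
  boolean-array oracle.
* Sites on chromosomes without genes go to an explicit unassigned sink,
  never silently dropped; empty inputs return empty (typed) results except
  where the operation is undefined (activity on fewer than two replicates,
  concordance with an empty side), which raise errors.
* Target genes missing from the expression table are counted silent, with
  a warning.
* All file outputs are plain TSV/JSON/BED with deterministic formatting;
  rerunning any stage with identical inputs is byte-identical (timestamps
  are confined to the run log).

## Problem sizes used in the test suite

Oracle equivalence runs on ≥100 random fixtures of ≤100 kb with per-base
boolean arrays. End-to-end recovery uses the default 2,000-gene /
1,000-target configuration once (shared across the recovery and senescence
checks) plus smaller cohorts (40–200 genes) for unit-level checks; these
sizes keep the whole suite in the low minutes while leaving the binomial
tolerances meaningful.

## Known limitations

* The published candidate lists this analysis style produces were manually
  curated ("edited to resolve ambiguities"); no deterministic rule can
  reproduce manual edits, so agreement with any specific published list is
  bounded by that curation, and the ambiguity rule here is the minimal
  deterministic reading.
* Whether the TES-proximal share is computed from summits or region
  midpoints is a genuine degree of freedom; the midpoint default is one
  choice, and a summit-based mode would require per-site summits that
  merged multi-antibody sites do not possess.
* The co-occupancy criterion is span-level: a long span satisfies it even
  if the CBX and RING evidence sit at opposite ends of the span. Shrinking
  `link_gap` tightens this at the cost of fragmenting loci.
* No replicate-reproducibility statistics (IDR), no FPKM computation, no
  3D-contact or enhancer-aware assignment.
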
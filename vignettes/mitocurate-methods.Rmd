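---
title: "Curating single-strand mitochondrial genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating single-strand mitochondrial genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocurate)
```

## The problem

Flatworm (triclad) mitochondrial genomes are compact circular chromosomes
(~15–27 kb) with twelve protein-coding genes, two rRNAs and a full tRNA set,
all encoded — and transcribed — on a single strand. Standard annotation
engines struggle with them for three connected reasons: the clade uses the
echinoderm/flatworm genetic code (translation table 9), several genes
initiate at noncanonical codons (notably TTG), and long noncoding regions
and unannotated ORFs (a putative *atp8*) sit between genes. This package
implements a curation workflow that addresses each point and a synthetic
genome generator that plants known truth so every stage can be measured.

## The genetic code and ORF model

Translation uses table 9: relative to the standard code, AAA codes Asn,
AGA/AGG code Ser and TGA codes Trp, leaving TAA and TAG as the only stops.
The initiator set defaults to \{ATG, GTG, TTG\} (`codon_table("9+TTG")`);
the canonical table-9 set \{ATG, GTG\} is available as `codon_table("9")`.
Any initiator is read as formyl-Met.

`scan_orfs()` emits **stop-to-stop** segments of at least 80 codons on the
three sense frames, read circularly across the origin (the sequence is
conceptually doubled; an ORF can never exceed the genome length, and a
stop-free circular frame is emitted capped at the frame length and flagged).
Segments are stop-bounded rather than start-anchored because the start is
precisely what cross-species homology is later asked to decide: similarity
frequently extends upstream of the most upstream ATG. Every in-frame
initiator inside a segment is recorded as a candidate start. Abbreviated
stops (T/TA completed by polyadenylation) are not modelled; a segment simply
ends at the next full stop.

## Start-codon refinement

For a panel of species, each species' ORFs are matched to reference proteins
by exact Smith–Waterman local alignment (BLOSUM62, gap open 11 / extend 1 —
a gap of length $k$ costs $11 + k$). Raw scores with a threshold of 50
replace E-values: the search space is a dozen genes, not a database, so
exactness is cheap and database-size statistics add nothing. Each gene's
members are then multi-aligned by deterministic center-star progressive
alignment (the member with the highest summed pairwise score is the center;
others are aligned to it ends-free; "once a gap, always a gap"). For a
handful of closely related sequences this is reproducible and adequate, and
it keeps the artifact free of external aligner binaries.

The start-selection rule formalizes "maximize upstream homology, minimize
the distance between genes" as an additive score. For candidate start $c$ of
one member,

$$ S(c) \;=\; \#\{\text{columns with occupancy} \ge \theta \text{ at or
downstream of } c\} \;-\; \lambda \cdot \max(0,\ \text{overlap of } c
\text{ with the upstream gene}) $$

with occupancy threshold $\theta = 0.5$ and overlap penalty $\lambda = 1$
per base, both exposed as arguments. Ties prefer ATG over GTG over TTG, then
the most-upstream position. Pure intergenic gap length is reported
(`upstream_gap`, negative for overlaps) but not scored: conserved gene
cartridges in these genomes legitimately overlap, so distance alone is not
evidence. The two defaults are genuinely free parameters — they
operationalize a judgment that curators otherwise apply by eye — and the
synthetic-recovery experiments measure this operationalization, not the
underlying judgment.

## Transcription evidence

Coverage tracks are per-base stranded depth vectors. Three products:

* `strand_fraction()` — the single-strand transcription test,
  $\sum \text{sense} / \sum(\text{sense}+\text{antisense})$, excluding rRNA
  loci by default because antisense signal there is expected rRNA carry-over
  in polyA-selected libraries. Zero-coverage tracks return `NA`: the
  fraction is undefined, not 0 or 1.
* `call_transcribed_regions()` — positions at or above a per-base floor
  (default half the mean-depth threshold) are segmented, segments closer
  than `merge_gap` (50 bp) merge, and merged segments pass if they are
  ≥ 100 bp (the conventional lncRNA floor) with mean depth above threshold.
  A region overlapping annotation over less than 10 % of its length is
  labelled intergenic — a lncRNA candidate.
* `detect_dropoffs()` — for every inter-base boundary, the score
  $\log_2\frac{\bar d_\text{left}+1}{\bar d_\text{right}+1}$ over 50 bp
  circular flanks; local extrema with $|score| \ge 2$ are kept, greedily
  thinned (strongest first) to a 100 bp minimum separation. The +1
  pseudocount keeps zero-coverage flanks finite. Down-steps mark putative
  transcript cleavage sites; up-steps can corroborate start calls
  (`annotate_starts_with_dropoffs()`, 10 bp tolerance).

Published descriptions of transcribed mitochondrial noncoding regions give
approximate depths, not a calling algorithm; the floor–merge–filter scheme
and every constant above are this package's formalization, kept in
arguments rather than code.

## Gene-order comparison

Gene orders are circular label sequences rotated to a canonical anchor
(cox1), with tRNAs distinguished from "major" genes (CDS + rRNA). The
"tRNA difference" between two genomes is operationalized as the **minimal
tRNA deletion set**: the smallest set of tRNA labels whose removal from both
circles makes them identical up to rotation. The search is exhaustive over
subsets up to `max_k = 4` (at most a few thousand candidates for 22 tRNAs),
so the reported value is exact or an explicit lower bound flagged
unresolved. Orientation is ignored — every gene sits on one strand, so
orders are unsigned circular permutations. `conserved_blocks()` intersects
circular successor relations across a panel, reporting maximal runs
contiguous in every genome — the cob–nad4L–nad4 cartridge test.

## Noncoding regions and candidate ORFs

Noncoding regions are maximal circular intervals free of CDS/rRNA. tRNAs do
not interrupt a region; they are recorded and their bases subtracted from
the reported length (the span-inclusive convention is available via
`exclude_trna_length = FALSE`). This convention makes "a long region
interrupted only by a single tRNA" a single catalogue entry with a
noncoding length proper. Regions of ≥ 500 bp are classed long.

Candidate ORFs inside noncoding or transcribed regions are **start-anchored**
(min 25 aa), unlike the genome-wide scan, because nothing homologous defines
their upstream extent; for each terminating stop the most upstream initiator
wins. Their protein architecture is described by two heuristics standing in
for domain-database predictions: Kyte–Doolittle sliding-window hydropathy
(window 19, cutoff 1.6 — the standard published constants) for transmembrane
segments, and a signal-like N-terminus rule (a ≥ 7-residue hydrophobic
stretch inside the first 30 residues preceded by a K/R within the first 5).
Both are labelled heuristics and make no claim of equivalence to trained
predictors. Threshold crossings are decided on exact integer sums of the
one-decimal hydropathy values, so results do not depend on floating-point
accumulation order.

## The synthetic generator: what it emulates, and what it does not

`simulate_genome()` / `simulate_panel()` / `simulate_coverage()` define the
study conditions:

* a 20 kb circle; 12 proteins (95–630 aa, cox1 fixed at 630), rRNAs of 900
  and 650 nt, 22 tRNAs of 60–70 nt, all on one strand; gaps of 60–80 bp; the
  cob–nad4L–nad4 cartridge always contiguous; the whole circle randomly
  rotated so features wrap the origin in general position;
* proteins are random amino-acid strings back-translated with uniform
  synonymous codons — interiors are stop-free by construction; each CDS
  opens at a start codon drawn from the mix (TTG 0.5, ATG 0.4, GTG 0.1,
  reflecting the clade's observed predominance of TTG) and the preceding
  gap ends with an in-frame TAA, so the stop-to-stop segment opens exactly
  at the planted start;
* a long noncoding region interrupted by a single tRNA (trnS1) hosts three
  planted transcribed intervals of 1000/710/1100 bp at 2000×/15×/250× —
  the depths and sizes reported for such regions in sequenced triclads —
  and a 321 bp gap after nad2 hosts an unannotated 60-codon TTG-anchored
  ORF with a signal-like N-terminus and a 21-residue transmembrane core;
* coverage: one plateau per transcription unit (each CDS/rRNA; the cartridge
  as a single unit, as its overlapping genes preclude independent
  processing), log-uniform 10–2000×, Poisson noise per base, background 1×,
  tRNAs at background (polyA selection depletes them), antisense depth
  Poisson at 2 % of sense inside rRNA loci only;
* panels: species 2..n substitute amino acids at a configurable rate
  (default 0.2; recovery is asserted up to 0.3) with the initiator fixed
  and synonymous codons redrawn, and relocate a configurable number of
  tRNAs into a *different major-gene interval* — since major genes cannot
  be deleted, each relocated tRNA provably must be in any reconciling
  deletion set, so the planted count is exactly the minimal deletion-set
  distance.

Features of real data deliberately **not** emulated: indel evolution,
within-gene rate variation, abbreviated stop codons, read-level artefacts
(the generator plants depth, not reads), tRNA secondary structure,
duplicated tRNA labels, and upstream truncation noise. Passing recovery
tests therefore demonstrates that the algorithms invert the generative
model they were specified against — not that they are robust to every
artefact of real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout (GenBank convention);
  `end < start` wraps the origin; BED/bedGraph I/O converts to 0-based
  half-open at the boundary. A feature may never cover the whole circle.
* Only "+" strand features are accepted; antisense annotation input is an
  error by design, not an oversight.
* Alignment tie-breaking among co-optimal alignments follows the backend's
  deterministic choice; scores (the contract-tested quantity) are exact.
* Region calling on the *sum* of two tracks can, in general, call fewer
  bases than on one addend (a high plateau diluted by a long near-floor
  extension can fail the mean filter after merging); monotonicity holds for
  the plateau-style tracks the generator produces and is asserted there.
* Zero-length gaps, empty regions, proteins shorter than a hydropathy
  window, groups with fewer than two members, and ORF-less loci all return
  empty/flagged results rather than errors, except where a precondition is
  stated (signal rule needs ≥ 15 aa; alignment needs non-empty sequences).

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run: oracle equivalence on
1000 random alignment pairs (≤ 30 aa), 100 random genomes (≤ 3 kb), 200
random gene orders and 1000 random proteins; and recovery experiments over
20 seeds — 4-species panels at 30 % divergence for start codons, single
genomes for lncRNA/drop-off recovery, and 2-species panels for tRNA
relocations k = 1, 2, 3. These sizes give exact expectations (100 %
recovery under the stated conditions) in a few minutes of compute.

## Known limitations

* The start-selection score is one formalization of a verbal rule; other
  operationalizations (e.g. scoring conservation of the initiator column
  itself) are plausible and would differ on adversarial inputs.
* ORFs without homologs are resolved by the overlap/upstream terms alone,
  which is the weakest setting of the rule.
* The deletion-set distance is not a metric (no triangle inequality) and is
  reported as a lower bound when the exact search exceeds `max_k`.
* GenBank flat files are not parsed; annotations enter as TSV (or GFF3
  written by this package).
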
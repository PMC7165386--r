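---
title: "Annotating Academ DNA transposons: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating Academ DNA transposons: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(academscan)
```

## The problem

Cut-and-paste DNA transposons are delimited by terminal inverted repeats
(TIRs) and, upon integration, duplicate a short stretch of host sequence on
both sides of the new copy (the target site duplication, TSD). TSD length
is a mechanistic signature of the transposase, and in the Academ
superfamily it separates two deep lineages: AcademH (9–10 bp TSDs; a
transposase and a superfamily 2 helicase encoded in opposite directions)
and AcademX (3–4 bp TSDs; one large transposase–XPG protein). AcademHP, a
sublineage of AcademH, carries one or two Cys4-His-Cys3 PHD fingers inside
the transposase, between the second catalytic D and the final E.
Non-autonomous derivatives share termini with an autonomous family but
encode nothing.

Annotating a family therefore means: finding its genomic copies,
reconstructing the complete repeat unit, locating its boundaries precisely
enough to read off TIRs and TSDs, and reading its coding layout. This
vignette explains how each stage is modelled, which parameters matter, and
what the synthetic benchmarks do and do not demonstrate.

## The synthetic data generator

`lineage_profile()` fixes the generative parameters of one family: allowed
TSD lengths and sampling weights, TIR length, element length, terminal base
classes, coding cassettes, per-copy divergence, and truncation probability.
The built-in profiles encode the field's reported values: fungal AcademH
9-bp TSDs; animal AcademH 9/10-bp; AcademX 3-bp (animals) and 4-bp (red
alga); TIR extremes of 526 bp (`AcademH-1_LoTr`), 575 bp
(`AcademH-16_CVi`) and 8 bp (`AcademH-2_PSt`); pyrimidine 5′ / purine 3′
termini. Element lengths (2.6–4.3 kb) are chosen to hold the coding
cassettes with realistic spacers; they are generator conventions, not
biological claims.

`make_element()` builds one element: a random TIR (first base C/T, the 3′
copy is its reverse complement, hence ends in G/A), interior spacers, and
reverse-translated protein cassettes bracketed by stop codons so that the
planted ORFs are exactly recoverable. Protein templates place the DDE triad
with D–D spacing 165 (mid-range of the diagnostic 138–192 window), a GxxH
motif 5 residues after D2, and the catalytic E 220 residues after D2;
spacer residues are drawn from an alphabet free of C/D/E/G/H so the planted
motifs are the only motif matches. Two generator details matter for exact
benchmarks:

* three bases immediately interior to each TIR are forced non-complementary,
  so the planted TIR length is the unique maximal-scoring terminal span;
* flanks and TSDs are never mutated — divergence and truncation apply to
  element copies only — so planted parameters are exactly recoverable at
  divergence 0, and excising each insertion plus one TSD copy restores the
  ancestral contig byte-for-byte (`restore_ancestral()`).

`plant_insertions()` duplicates a k-bp target at each insertion point
(k sampled from the profile), forbids overlap and nesting, and records the
full ground truth. Non-autonomous profiles inherit the termini of the first
autonomous family planted in the same genome, since terminal homology is
the only evidence by which such elements are recognizable. The background
is i.i.d. uniform (optionally GC-biased) — it reproduces none of the
repeat structure, GC heterogeneity, or segmental duplication of real
genomes, so passing benchmarks demonstrates correctness of the machinery,
not expected sensitivity on real assemblies.

## Homology scanning

`scan_genome()` is a transparent seed-and-extend scanner: exact k-mer seeds
(default word size 12) grouped by diagonal, ungapped x-drop extension
(default drop-off 20 at +1/−1 scoring), identity ≥ 0.7 and length ≥ 50 to
report. The published workflow's search tool does not document its internal
parameters; these defaults are package parameters, not claims about that
tool. Ungapped extension is the default because the simulator's divergence
model is substitution-only; on indel-rich real data the chaining step
(`merge_hits()`, dynamic programming over collinear fragments with bounded
gaps) reconstructs fragmented copies. Elements with long TIRs match their
own reverse complement at the termini; these palindromic self-hits are
removed by containment dedup (a hit wholly inside a higher-scoring hit on
the same contig is dropped).

## Consensus and boundary confirmation

Families are single-linkage clusters of hits (pairwise identity ≥ 0.8 over
≥ 0.5 of the shorter sequence, computed with the package's own scanner; an
independent alignment-based oracle backs this in the tests). The top 10
members are extracted with 1000-bp flanks and star-aligned onto the
representative — direct column stacking when extractions are equal-length
and near-identical, pairwise global alignment otherwise. Consensus is the
per-column plurality with alphabetical tie-break (equivalent to strict
majority whenever one exists); majority-gap columns are dropped.

Boundary confirmation (`refine_until_tsd()`) operationalizes "extend the
flanks until TSDs are detected". All boundary pairs within a window of the
current candidate are scored by how many members show an exact flanking
duplication at the same consensus columns. Three guards make this reliable:

1. **Host-sequence distinctness.** A true TSD is duplicated *host*
   sequence, so its sequence differs between insertion sites; candidate
   boundaries whose supporting "TSDs" are identical in every member are
   element-internal repeats and are rejected. (Sequences are compared in
   element orientation so plus- and minus-strand members of the same
   artifact cannot masquerade as distinct.)
2. **Independent support.** Members whose flanked extractions map to the
   same genomic span (adjacent copies) count once.
3. **Chance-support bound.** The probability that s of n members show a
   ≥ k-bp duplication at one boundary pair by chance is bounded by
   `choose(n, s) * ((4/3) * 4^-k)^s`; multiplied by the number of pairs
   examined, it must fall below 0.01. A consequence worth knowing: a
   3-bp TSD needs about 4 agreeing copies to be confirmable, while a 9-bp
   TSD is confirmable from 2 — short-TSD families require more copies.

The search window is ±50 bp, widened once to ±100 bp if unconfirmed;
`unconfirmed` after `max_iter` rounds is a valid outcome (families without
duplications stay unconfirmed by design). After confirmation, every member
is annotated at the family boundaries mapped through the star alignment —
not re-searched individually, which both matches how per-family figure
evidence is read and avoids the ~1% per-member chance of a longer spurious
duplication somewhere in a ±50 bp window.

## TIR and TSD calling

`call_tsd()` returns the largest k in [2, 12] with exact equality between
the flank suffix and prefix; matching is exact because the evidence for the
published TSD lengths shows identical copies (a mismatch-tolerant mode is
deliberately absent by default). kmax = 12 leaves margin above the reported
3–10 bp range.

`detect_tir()` compares the element prefix with the reverse complement of
its suffix, ungapped from the termini inward. The reported length is the
maximal-scoring prefix under +1/−p scoring with p = identity/(1 −
identity), so the score is non-negative exactly at the identity threshold
(0.8 by default); the span must start and end on a match and reach 8 bp.
The maximal-score rule (rather than "longest span above threshold") is what
makes a 526-bp perfect TIR report exactly 526: a long perfect repeat
followed by random sequence would otherwise absorb ~25% chance matches for
over a hundred positions before dipping below 80% identity. How internal
mismatches should count against a "526-bp TIR" is not defined anywhere we
know of; the identity threshold is exposed as a parameter and this scoring
is our documented interpretation.

`refine_boundaries()` (the single-copy path) ranks boundary pairs by TSD
length among TIR-bearing pairs first — an accepted element requires the TSD
adjacent to the TIR, and requiring the TIR suppresses off-by-a-few spurious
duplications — falling back to TSD-only and then TIR-only ranking so
TIR-less candidates remain annotatable. Acceptance applies the strict
single-copy rule (TIR > 10 bp and adjacent TSD > 8 bp) and, for multicopy
elements, TSD ≥ 3 bp with ≥ 2 member support.

## Coding architecture

`find_orfs()` is intron-naive: maximal stop-to-stop ORFs ≥ 100 residues in
all six frames, no start-codon requirement. Real AcademH elements usually
contain introns, so on real genomes this module should be fed
externally-predicted CDS instead; the simulator plants intron-less
cassettes, which is the main deliberate gap between the benchmark and real
data. Motif scanners use documented patterns: the DDE triad with D–D
spacing 138–192, `[GAEQ]xxH` within 20 residues after D2, and E 150–350
residues after D2 (the window accommodates the α-helical insertion domain);
SF2 helicase as ordered Walker A / DExH-DExD / QxxGRxxR motifs; PHD as
Cys4-His-Cys3 and CCHH fingers with bounded spacers. XPG-nuclease and Cys8
zinc-finger patterns are placeholders (no residue-level description is
available); they are used symmetrically by the generator and scanner and
validated only on synthetic cassettes. Architecture calls follow the
lineage layouts; simultaneous helicase and XPG evidence is contradictory
and yields `other` with a note.

## Classification

The decision table uses a TSD window of [8, 10] for AcademH (the
single-copy rule says "> 8 bp", reported values are 9–10, and related
non-autonomous elements show 8–9 bp) and [3, 4] for AcademX; both windows
are configurable. AcademHP requires AcademH evidence plus ≥ 1 PHD finger.
Elements with no coding capacity become non-autonomous only on terminal
homology to a classified autonomous family (identity ≥ 0.8 over ≥ 50 bp of
each terminus); otherwise they stay unclassified with partial confidence —
including the real "no clear TSDs" situation, which is representable as a
TSD length of 0 with family membership still reportable by homology.
`alignment_stats()` summarizes a supplied transposase-domain alignment
(sequence count, ungapped length range, conserved columns at a 0.95
threshold, D–D spacing range given catalytic columns); tree building is out
of scope.

## Numerical and reproducibility choices

All coordinates are 0-based half-open internally and 1-based inclusive in
exported GFF3. Consensus ties break alphabetically; boundary ties break
leftmost. The pipeline itself uses no randomness — identical inputs give
byte-identical outputs — and all generator randomness flows from explicit
seeds. Test and acceptance problem sizes (genomes of 120–500 kb, 30
insertions per acceptance run, 20 simulated families per lineage with 4
copies each) are chosen so the full validation completes in minutes on one
CPU while still exercising every stage; 4 copies per family is the minimum
at which 3-bp TSDs pass the chance-support bound.

## Known limitations

Uniform background; substitution-only divergence by default; intron-naive
ORF finding; no nested or tandem insertions (excluded by the generator and
unhandled by the boundary caller); two-member families cannot confirm short
TSDs; chromosome-scale performance beyond tens of megabases and
protein-vs-DNA search are out of scope.
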
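---
title: "Annotating genes from full-length transcript evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating genes from full-length transcript evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartanno)
library(dplyr)
```

## The problem

*Ab initio* gene predictors are least reliable exactly where genes are most
interesting: many exons, short exons, long introns, weak start signals.
Single-molecule long-read sequencing of cDNA changes the evidence situation,
because a single read can span an entire transcript — both synthesis
primers and the poly(A) tail are still attached, so a read can be *proven*
to represent a complete molecule rather than a fragment. smartanno
implements a desk-scale, fully testable version of the annotation workflow
built on that idea:

1. **classify** raw cDNA reads into full-insert and partial reads
   (`classify_reads()`),
2. **validate** an existing gene annotation against spliced long-read
   alignments (`validate_gene_models()`),
3. **derive** new gene models where the annotation is missing or wrong
   (`derive_gene_models()`),
4. **denoise** deep short-read mRNA-seq coverage so it helps rather than
   confuses a predictor (`reduce_expression_noise()`),
5. **emit hints** — the extrinsic-evidence records an external gene
   predictor consumes (`isoform_to_hints()`, `repeats_to_hints()`,
   `emit_extrinsic_config()`),
6. **migrate and evaluate** annotations across versions
   (`transfer_stable_ids()`, `evaluate_predictions()`,
   `reciprocal_best_hits()`).

A deterministic simulator (`simulate_annotated_genome()` and friends)
generates genomes, reads, alignments and coverage with known ground truth,
so every rule above is exercised end to end without external data.

All coordinates inside the package are 0-based half-open; GFF emission is
1-based inclusive. Minus-strand features store exons in ascending genomic
order; transcript order is derived where needed.

## Full-insert read classification

A read is *full-insert* when the 5' primer, the 3' primer and a poly(A)
tail are all present. Primers are located by semi-global alignment (primer
global, read local, unit mismatch/indel costs) within the terminal 100
bases of the read; a match requires identity `1 - edits/len >= 0.80`. The
edit-distance form matters: defining identity as *matched bases / primer
length* lets an alignment scatter 20 matches of a 24-mer across a random
100-base window via cheap gaps, which produces spurious primer calls. Under
the edit-distance form, two mismatches in a 24-mer still give
`22/24 = 0.917`, but chance matches in random sequence score far below the
cutoff.

The poly(A) tail is the longest window ending at the 3'-primer start (or
the read end) with A-fraction at least 0.90 and length at least 20 bases,
subsequently stripped of leading non-A bases. The stripping step is a
deliberate refinement: with a 10% tolerated non-A fraction, the raw longest
window can absorb up to `len/9` trailing transcript bases, so a tail of 36
A's would otherwise swallow four 3'-UTR bases. A tail must start on an A.

If the reverse complement of a read carries the stronger primer evidence,
the read is antisense and is flipped before trimming. Reads whose located
primer regions overlap are flagged `conflicted` and never called
full-insert. The upstream length/quality prefilter (`prefilter_reads()`)
removes subreads under 50 bases and reads with predicted accuracy below
0.75; reads without an instrument-reported quality pass, because the cutoff
is defined on reported values only.

The primer identity cutoff (0.80), search window (100 bases), minimum tail
length (20) and tail A-fraction (0.90) are this package's declared
defaults; the published protocol delegated primer detection to an external
tool without printing its thresholds.

## Validating gene models with spliced alignments

Alignments first pass the *full-length* filter: a read must align with at
least 90% of its length **and** miss at most 50 bases, and must map to a
single genomic locus. The two conditions are read as a conjunction; the
50-base cap exists because long reads suffer deletion errors, so a
percentage alone would be too permissive for long reads and too strict for
short ones.

A model is then

* `validated` — at least one filtered alignment overlaps its exons, *every*
  overlapping alignment has exactly the model's intron chain (same number,
  order and boundaries of introns), and at least one overlapping alignment
  covers both the start and the stop codon;
* `contradicted` — some overlapping alignment carries a different chain;
* `unsupported` — nothing overlaps (or chains agree but no read spans both
  terminal codons; the three-state contract has no better place for this
  rare case, and "insufficient support" describes it accurately).

UTR lengths are free to vary: only the intron chain and the terminal
codons are binding. Codon coverage is checked on the first and last three
*coding* bases projected through the exons — a terminal codon may straddle
an intron, so checking the genomic CDS-span ends would demand coverage of
intronic bases. Models without a CDS raise an error rather than silently
validating. Single-exon models degenerate naturally: any overlapping
intron-free alignment covering both codons validates them.

Genes whose span touches the first or last 5,000 bases of a scaffold can
be removed with `exclude_border_genes()`; truncated scaffold ends tend to
carry incomplete genes.

`classify_orf_coverage()` implements the related read-centric measure: an
alignment is `full_orf` when it covers every coding base of the gene, and
`full_orf_with_utr` when it additionally covers 10 genomic bases beyond the
CDS on both sides.

## Deriving gene models from read clusters

Where no (correct) annotation exists, models come from the reads alone:

1. cluster full-length alignments by **identical intron chain** on
   overlapping spans (`cluster_by_intron_chain()`); loci are connected
   components of span overlap per strand;
2. per locus keep the **most abundant isoform** with at least two
   supporting reads (`select_isoforms()`); a single spliced read qualifies
   only when every junction is independently confirmed by short-read
   intron evidence. Ties go to the longer genomic span, then the leftmost
   start — the paper-scale protocol does not specify a tie rule, so ours
   is declared and tested. Intron-free singletons never qualify through
   evidence (they have no junctions to confirm);
3. transcript boundaries are the **median** alignment start and end of the
   members (`derive_boundaries()`); even counts use the lower median so
   the boundary is always an observed coordinate;
4. the exon chain is spliced out of the genome and the **longest
   forward-frame ORF** (`find_orf()`, default minimum 100 codons) supplies
   the CDS. This is a deliberately simple stand-in for a dedicated ORF
   caller; candidates without a qualifying ORF are emitted without CDS and
   flagged `orf=none`.

Candidates overlapping an already-accepted gene by one or more exon bases
are dropped, mirroring the "new, non-overlapping models only" role this
step plays downstream of validation.

## mRNA-seq noise reduction

Deep short-read coverage boosts evidence for weakly expressed genes but
adds background: incompletely spliced mRNA and rare isoforms blur intron
boundaries. Four rules clean it, in this order:

1. **Peak normalization** — in non-overlapping 1,000-base windows of each
   contiguous track, subtract 10% of the window's 95th-percentile depth
   (nearest-rank definition, index `ceiling(0.95 n)` of the sorted
   window), clamping at zero.
2. **Intron-hint shadowing** — whenever two intron hints overlap and their
   relative support difference `(mult_a - mult_b)/mult_a` exceeds 0.90,
   the weaker hint is dropped. The difference is normalized by the
   *higher* multiplicity, and hints are processed in descending
   multiplicity against survivors, which reaches a fixed point in one
   pass: a hint's potential removers are all settled before it is
   considered.
3. **Intronic attenuation** — an intron hint at most 50 kb long whose
   junctions both show a coverage drop of at least 50% (mean of the 10
   intron-side bases vs. the 10 exon-side bases) has every intronic depth
   reduced by half the adjacent exon coverage (the mean of the two
   exon-side means). Junction statistics are computed on the
   pre-attenuation snapshot and reductions clamp at zero, which makes the
   result independent of intron order (clamped subtractions commute).
   Positions absent from the coverage table count as depth zero. Overlap
   between hints ignores strand: coverage is unstranded.
4. **Anchor promotion** — intron hints supported by at least 50 reads gain
   a duplicate with source `M`; the predictor configuration gives
   `M`-source hints an overwhelming bonus (1e+100), effectively forcing
   those introns.

Both coverage filters are dominance-preserving (never increase a depth,
never go negative), and the whole stage is checked against an independent
brute-force implementation on random integer fixtures, where agreement is
exact.

## Hints and predictor weights

A selected isoform becomes one hint group: internal exons as `exon` hints,
terminal exons as `exonpart` (their outer boundaries are median read ends,
not confirmed splice sites), introns as `intronpart`, all sharing a
deterministic group id (scaffold + start + chain hash). Source `E` marks
ordinary expression evidence, `M` marks anchors. To stop the predictor
from appending exons to a group, 1-base `irpart` (intergenic) hints are
placed 50 bases outside each group span — at `group_start - 51` and
`group_end + 50` in 0-based coordinates — and dropped when they fall off
the scaffold.

Repeat intervals become `nonexonpart` hints with source `RM` at priority
6, above the expression priority of 4, with bonus 1e+10 (raised from the
predictor default 1.01): repeats then reliably exclude exons even under
conflicting expression signal, without hard-masking the assembly. The
intron malus is tightened from 0.34 to 0.001, penalizing predicted introns
that lack hint support. `emit_extrinsic_config()` renders these numbers as
a byte-stable text fragment.

## Identifier transfer, training selection, evaluation

`transfer_stable_ids()` moves stable gene ids between annotation versions
by summed CDS-overlap: each old gene goes to the new gene with the longest
overlap; one-to-many cases resolve to the longest partial overlap;
many-to-one cases resolve to the reciprocal best (the old gene with the
largest overlap wins, others stay unassigned); exact ties resolve greedily
left-to-right along the scaffold, preserving gene order. The result is
injective by construction, and translation-invariant because only overlaps
enter the rules. Remaining new genes receive fresh ids in positional
order.

`select_training_genes()` prepares predictor training sets: genes with CDS
length not divisible by three are dropped, then for every protein pair at
identity ≥ 0.80 the shorter CDS is dropped (pairs in descending identity;
equal lengths drop the lexicographically later id), and the survivors are
split into seeded random training/test sets.

`evaluate_predictions()` scores predictions at three levels: exact exon
matches, exact transcript matches (all exons identical), and per-base UTR
agreement, with sensitivity `TP / reference features` and precision
`TP / predicted features inside the evaluation regions`. An empty
prediction reports precision 0 with `precision_defined = FALSE` instead of
`NaN`. `reciprocal_best_hits()` applies the standard 1:1-orthology proxy
(e-value ≤ 1e-5, alignment ≥ 50% of query length, best hit by bitscore
with e-value and subject-id tie-breaks, mutual-best pairs only), and
`stress_specific_genes()` selects genes with zero control coverage and at
least 90% CDS coverage under some stress condition.

## What the simulator emulates — and what it does not

`simulate_annotated_genome()` builds scaffolds of non-overlapping genes
with `ATG..stop` CDSs free of internal stops, canonical `GT..AG` introns,
and UTRs on both sides. Defaults target a compact plant genome: 2–8 exons
per gene (mean ≈ 5), introns of 80–400 bases, UTRs of 60–300 bases,
proteins of 110–320 codons (~1 kb CDS). Two constructions make ground
truth exact rather than merely probable: a stop codon in all three frames
sits immediately upstream of the annotated ATG (so the longest transcript
ORF *is* the annotated CDS), and the 3' UTR ends on six non-A bases (so
the poly(A) boundary is unambiguous under the 0.90/20-base tail rule).
Splice sites are kept at least 12 bases away from the CDS boundaries so
the 10-base UTR margins project onto exonic sequence.

`simulate_full_insert_reads()` emits `P5 + spliced transcript + poly(A) +
revcomp(P3)` reads with optional boundary jitter (emulating variable UTR
lengths), per-base indels, antisense emission, and labelled negatives
lacking a primer or the tail. True spliced alignments are recorded
*before* errors — the package consumes alignments, it does not produce
them, so the simulator stands in for an error-free spliced aligner.
`simulate_expression()` draws exonic depth from Poisson(100) and intronic
leakage from Poisson(8) by default, gives every true intron a hint with
multiplicity ≈ exon depth, and plants weak "rare isoform" introns
(multiplicity ≤ 3) overlapping true ones. `mutate_models()` corrupts
models (junction shifts, dropped exons, gene fusions) with a log, so
validation and evaluation outcomes are checkable.

Passing tests on these fixtures shows the *rules* are implemented exactly
and behave as designed under controlled noise. It does not show
performance on real data: the simulator has uniform base composition, no
sequencing-chemistry error profile, no alternative splicing, no
transposable elements inside introns, and alignment errors are limited to
an optional block-edge perturbation. Conclusions about real genomes still
require real reads and a real aligner.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in a few minutes: 200-gene genomes for validation,
derivation and classification checks (5–10 reads per gene, i.e. 1,000–
2,000 reads), 100 random fixtures for the noise-reduction equivalence and
RBH checks, and 100 perturbed annotation pairs for the id-transfer
properties. Determinism comes from a single integer seed per generator
call; all randomness flows through R's RNG under `withr::with_seed`.

Depths are kept as doubles (wiggle output writes integers compactly and
fractional values at full precision); percentile is nearest-rank rather
than interpolated so integer fixtures stay integral; medians of even
member counts take the lower value so derived boundaries are observed
coordinates; hint output is sorted (scaffold, start, end, kind, source) so
emission is stable under input permutation.

## Known limitations

* Validation treats the intron chain as strand-specific via the stored
  strand of the alignment; an aligner that reports unstranded intron-free
  alignments on the opposite strand would count as contradiction.
* The ORF caller considers forward frames of the sense transcript only and
  picks the longest ORF; genes where the true CDS is not the longest ORF
  (uORF-rich 5' UTRs) would be mis-annotated, as with any longest-ORF
  heuristic.
* `transfer_stable_ids()` assumes old-CDS placements on the new assembly
  are given; it does not align.
* The noise-reduction stage assumes per-base coverage fits in memory per
  scaffold; chromosome-scale tracks would need a chunked implementation.
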
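---
title: "Recovering circular genomes from metagenome bins"
author: "circbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering circular genomes from metagenome bins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circbin)
```

## The problem

Metagenome binning yields *bins* — sets of contigs hypothesised to come from
one genome — that are almost never complete. For small bacterial genomes
(a few hundred kb to ~1.5 Mb, as in many host-associated and reduced-genome
clades), a bin with a handful of long contigs at good coverage is often only
a few kilobases of unassembled sequence away from a closed circular
chromosome. `circbin` closes that gap with *digital primer walking*: it
recruits read pairs that share k-mer content with the bin ("baiting"),
extends and merges the bin's contigs under a strict read-coherence
discipline, and repeats the two steps until one of three outcomes:

* **Circularization** — a single contig with a significant, exact repeat at
  its two ends: the assembly has walked all the way around the circle;
* **Idempotence** — an iteration changes nothing; the walk has stalled
  (typically at coverage gaps or unresolvable repeats);
* **Chaos** — the bin shatters into many short contigs, the signature of a
  bin whose original contigs were not read-coherent to begin with.

A circularized sequence then has to pass quality gates before it is called
a genome, and its ribosomal RNA operon layout can be classified.

## The iterative loop

Each iteration performs:

1. **Baiting.** A canonical k-mer index (default `k = 33`, odd so that no
   k-mer equals its own reverse complement) is built from the current
   contigs. A read pair is recruited when *either* mate shares at least
   `min_hits = 1` k-mer window with the index; both mates are kept. The
   inclusive defaults deliberately over-recruit — the mate of a read
   anchored near a contig end reaches up to a fragment length beyond the
   end, and those outer mates are what the next extension round walks on.
   Reads matching several bins are kept for each; no disambiguation is
   attempted.
2. **Reassembly.** The built-in surrogate assembler alternates consensus
   extension of every contig end with exact-overlap merging until a
   fixpoint. It stands in for an external overlap-layout-consensus
   assembler, which can replace it through the `external_assembler()`
   command-template adapter.
3. **Filtering.** Contigs shorter than `min_contig_len` (1 kb) are dropped,
   then contigs whose estimated coverage deviates from the length-weighted
   median by more than 10% — the signature of contaminating sequence. The
   median is length-weighted so the contaminant being removed cannot drag
   the reference value with it. Filtering before the next bait round is
   equivalent to the restart-from-filtered-bin procedure a manual operator
   would use.
4. **Outcome detection** (`detect_state()`): circularization requires a
   single contig passing `assess_circularity()`; idempotence is exact
   equality of reverse-complement-normalised sequence sets; chaos is a
   `chaos_factor`-fold (3x) increase in contig count *with* an N50 drop.
   A shattered bin in practice looks like a handful of contigs exploding
   into a hundred-plus short pieces, which motivates the count condition;
   the N50 co-condition avoids flagging legitimate contig splitting early
   in a run. Chaos has no quantitative definition in the
   literature; this conjunction is this package's operationalisation.

## Read-coherent extension

`extend_end()` grows a contig's 3' end base by base. A read (either
orientation) votes on the next base while its alignment against the
trailing `min_overlap` window of the growing sequence is exact; a
mismatching vote suspends the read until the offending position has left
the window. New reads join when one of their anchor windows (offsets 0,
`min_overlap`, `2*min_overlap`, ... within the read) equals the current
terminal window, so a read with a sequencing error in its first bases can
still join at a later anchor.

Extension halts when:

* fewer than `min_support` reads back the best base (coverage exhausted);
* the two best bases tie exactly; or
* a **balanced conflict** arises: the runner-up base is carried by at least
  `min_support` reads *and* by more than a quarter of the winner's support.

The balanced-conflict rule is the load-bearing design choice. At the exit
of an exact repeat longer than the read span, the voting population is a
roughly even mixture of reads from the repeat's two genomic contexts; a
simple majority would pick a side by sampling noise and extend chimerically
exactly where extension should fail. A 2:1-or-worse split is astronomically
unlikely from sequencing error (errors are rare, dispersed, and split over
three alternative bases) but is the expected signal of a two-context
conflict, so extension stops. For the same reason `merge_contigs()` only
fuses ends with a *unique* overlap partner: two contigs terminating in the
same long repeat present two equally exact fusion candidates, and picking
the longer (or either) would hard-wire a possible misassembly.

Defaults: `min_overlap = 40` nt (an exact 40-mer anchor makes spurious
joiners negligible at any realistic library size), `min_support = 2`,
`max_step = 5000` nt per end per round. Two concordant reads behind an
exact 40 nt anchor are already strong evidence; demanding a third mostly
throttles the walk at the recruitment frontier, where coverage tails off
within one fragment length of the contig end, and slows gap closure without
a commensurate safety gain — the chimera-relevant protection comes from the
balanced-conflict and unique-partner rules above, not from the third read.
Once a contig's terminal self-overlap reaches `10 * min_repeat` (a closed
circle re-walking itself), its ends are no longer extended.

## Deciding circularity

`assess_circularity()` calls a contig circular iff

1. its exact terminal overlap (the longest string border) is at least
   `min_repeat = 100` nt;
2. that overlap is strictly longer than any *other* repeat in the contig,
   computed exactly on both strands (inverted repeats count; the
   terminal-copy correspondence itself and palindromes matching their own
   interval are excluded); and
3. the terminal repeat string occurs exactly twice in the contig, counting
   both strands — it matches no further repeat copy.

The repeat search is exact: duplicated 32-mers are seeded and maximally
extended for answers of 32 nt and up, and a descending window scan settles
lengths 1–31, so the reported competing-repeat length is the true maximum,
not a heuristic. `circularize()` trims the terminal copy (placing the
junction at position 1); `rotate_seq()` re-seats it, and the pipeline
reports a half-rotated FASTA so an external polisher can see the junction
away from the sequence ends.

Independent corroboration comes from paired-end topology
(`topology_from_pairs()`): a circular replicon assembled as a linear contig
shows pairs whose mates sit near opposite ends pointing outward, and
properly oriented pairs spanning the junction after half-rotation; a truly
linear molecule shows inward-pointing pairs at its ends and no outward
signature. Mates are mapped by exact substring search — reads with errors
simply abstain, which biases counts down but never fabricates evidence.

## Completeness and coverage gates

A circular sequence still has to look like a whole genome
(`completeness_report()`):

* all three rRNAs (16S, 23S, 5S) at the expected copy number (default 1,
  a parameter because the method's target clades are single-operon but the
  gate is reusable);
* a tRNA for each of the 20 standard amino acids
  (selenocysteine/pyrrolysine are reported, never required);
* RNase P RNA — nearly universally required for tRNA maturation, and
  therefore a sharp completeness probe. Diverged RNase P genes can score
  below the covariance model's noise cutoff, so `relaxed_rnasep_scan()`
  accepts hits down to `noise_cutoff - 5` bits (the reduction is
  configurable, and an absolute-threshold mode is provided because
  "reduce the threshold 5" is ambiguous between *by* and *to*); every
  sub-cutoff acceptance is flagged for manual curation;
* coverage evenness: minimum per-base depth at least 30% of the mean.
  Depth for a circular genome is computed circularly (reads spanning the
  junction are folded back), since linear mapping of a circular molecule
  fabricates a depth hole at the sequence ends. A warning is attached below
  30X mean coverage, the regime where reassembly outcomes degrade.

Annotations come in through `parse_cmsearch_tblout()`, `parse_trnascan()`
or GFF3; running the annotators themselves is out of scope (their command
lines are their own documentation), as are pileup-based polishing and
multi-replicon genomes.

## rRNA operon linkage

`classify_rrna_linkage()` types the 16S/23S/5S arrangement: **A** operonic
with empty spacers; **B** tRNAs in the 16S–23S spacer (same strand);
**C** tRNAs and/or protein-coding genes in the spacers; **D** unlinked by
distance — the downstream spacer exceeds `max_gap = 2000` nt with no chain
of same-strand genes whose consecutive gaps each stay within `max_gap`, or
an opposite-strand gene interrupts it; **E** unlinked by strand. Decision
order is E, D, then A/B/C by spacer content. Spacers are walked in the
direction of transcription (across the origin on circular genomes);
reported distances are minimum arcs and so never exceed half the genome.
Intra-operon gaps of 300 nt and more are conservatively counted operonic,
with a note so the call can be revisited. The 23S–5S relation is assessed
with the same rules and reported separately; a 5S on the opposite strand is
reported as unlinked with a note rather than forced into a type, and rRNA
copy numbers other than one are an error by design — the classifier
targets single-operon genomes.

## The synthetic-data module

`simulate_genome()` draws i.i.d. bases at a target GC and plants exact
repeat copies at random non-overlapping positions; `simulate_reads()` draws
fragments from a truncated normal (mean 400, sd 40 by default), wraps the
origin of circular genomes (which is what creates the outward-pair
topology signature), takes inner-facing 150 nt mates and applies i.i.d.
substitution errors; `simulate_community()` pools libraries at uneven
abundances; `make_feature_fixture()` lays out rRNA/tRNA/RNase P/CDS
features in the geometry of each linkage type. All generators are pure
functions of (spec, seed).

What the simulations *do not* emulate — and hence what passing tests do not
show about real data: indels and instrument-specific error profiles
(substitution-only by design, since the exact-overlap machinery under test
is substitution-tolerant via consensus while indel handling belongs to the
external assemblers), GC-dependent coverage bias, tetranucleotide
composition structure, strain mixtures, and chimeric source assemblies.
The chaos outcome in particular is exercised with constructed traces, not
generated de novo, because it originates in upstream misassembly.

## Study conditions used by the tests

The end-to-end suite recovers a repeat-free 200 kb circular target at 80X
inside a three-genome community (two 100 kb backgrounds at 30X), seeded
with three evenly spaced 60 kb fragments of the target — leaving three
~6.7 kb gaps — with 150 nt reads, 400 ± 40 nt fragments and 0.5%
substitution error, across five seeds. Per iteration a gap edge advances
roughly one fragment length (the recruitment frontier), so the three gaps
close in eight to nine iterations, inside the ten-iteration default
budget. The failure-mode suite plants a 1.5 kb exact repeat — longer than
the fragment length — with its copies inside two of the seed gaps, and
requires that the run never reach circularization: a repeat already
spanned by a seed contig has been resolved upstream by longer-range
information, so placing the copies in the unassembled gaps is the honest
version of the test. These sizes keep a full five-seed recovery sweep
within a few minutes on one CPU while leaving every distance (gap width,
fragment length, repeat length) in the same ordering as the real use case.

## Numerical and degenerate-input choices

* Ambiguity codes other than N are rejected at every boundary; windows
  containing N never match in baiting, anchoring or repeat finding.
* Canonical k-mers require odd `k`; even `k` is refused outright rather
  than silently accepted, because a reverse-complement palindromic k-mer
  has no well-defined canonical strand.
* Interleaved FASTQ pairing is positional (records 2i−1, 2i); read-name
  dialects are too inconsistent to parse.
* Consensus ties and conflicts halt rather than guess; every tie rule
  (merge ordering, contig processing order, fused-contig naming) is
  deterministic, so identical inputs and seeds give byte-identical
  outputs.
* Internal coordinates are the 1-based closed convention of
  `GenomicRanges`; 0-based half-open appears only at explicit conversion
  helpers.
* `coverage_evenness()` on an empty track, `rotate_seq()` out of range,
  abundances not summing to one, infeasible repeat placement, and a bin
  whose filtering removes every contig are all hard errors, not warnings.

## Known limitations

Repeats longer than the fragment length stall the walk by design — the
correct behaviour, but it means rRNA arrays and long IS elements need
longer-range information. Multi-replicon genomes (plasmids, secondary
chromosomes) are out of scope: each replicon is a separate bin at best.
Coverage below ~30X is flagged but not rescued. The built-in surrogate
assembler resolves nothing an exact-overlap consensus cannot; real
assemblers with scaffolding or graph cleaning can be substituted through
the adapter and will behave differently around tangles.
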
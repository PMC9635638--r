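---
title: "Assembly completeness forensics and targeted correction with asmrescue"
author: "asmrescue maintainers"
date: "`r Sys.Date()`"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly completeness forensics and targeted correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmrescue)
```

## Motivation

BUSCO classifications (Complete single-copy, Duplicated, Fragmented,
Missing) are the standard currency for judging the completeness of a de
novo genome assembly, but the classes are not as stable as they look: the
same gene can be fragmented in one assembly of a genome and complete in
another assembly of the *same* reads, flip class when a scaffold is merely
reverse complemented, or become duplicated through a failed merge of two
assemblies. `asmrescue` turns these observations into tooling, built
around four pipelines:

1. **Cross-assembly gene rescue**: tabulate BUSCO classes across
   alternative assemblies, find genes fragmented in a focal assembly but
   complete elsewhere, and translocate the complete copy into the focal
   assembly by k-mer anchoring of its flanking sequences.
2. **Seeded long-read subsampling**: draw reads within a length window,
   uniformly without replacement, until a target coverage of an estimated
   genome size is reached.
3. **Hybrid-merge diagnostics**: model the overlap/non-overlap (OVL/n-OVL)
   ratio rule that gates contig merging, and attribute duplicated genes in
   a merged assembly to merge failure or preexisting duplication.
4. **Gap-fate classification**: after long-read gap filling, decide for
   every original scaffold gap whether it was closed, partially filled,
   *overfilled* (flanks extended inward without meeting, growing the
   assembly without closing the gap), or cannot be resolved.

A fifth module, the synthetic-data generator, builds seeded toy genomes
and fixtures with exact ground truth; it is first-class, tested code and
the substrate for every end-to-end check in the package.

## The rescue procedure

For a focal assembly `F` with BUSCO table `T_F` and donor assemblies
`D_1..D_m` with tables `T_1..T_m`:

1. **Case enumeration** (`findRescuableGenes`). A gene `g` is a case when
   its class in `T_F` is Fragmented and its class in at least one donor
   table is Complete *single-copy*. Duplicated donor copies are never
   used: with two candidate source regions the translocation would be
   ambiguous. When several donors qualify, the highest BUSCO score wins
   and ties fall to the donor listed first, so runs are reproducible.
   Fragmented genes complete nowhere are reported with reason
   `no_complete_donor` rather than dropped, which keeps the
   identified-versus-total accounting reconstructible.
2. **Orientation syncing** (`determineOrientation`). Scaffold orientation
   is arbitrary between assemblies. The donor scaffold's k-mers are
   counted against the focal scaffold's k-mer index in both orientations;
   the majority orientation is accepted only when it has at least
   `minShared = 50` shared k-mers and at least twice the opposing count.
   Anything weaker is `ambiguous` and the case is skipped — a wrong
   orientation call would translocate a reverse-complemented gene.
3. **Flank anchoring** (`extractFlanks`, `anchorFlank`). The
   `flankLen = 1000` bp on each side of the donor gene are matched
   against the focal scaffold k-mer by k-mer (`k = 31`, exact matching).
   Only k-mers that occur *exactly once* on the focal scaffold count, and
   the matches must form a collinear, strictly increasing run covering at
   least `minMatchFrac = 0.8` of the flank's N-free k-mers. Uniqueness
   refuses repeat-borne flanks — the mechanism by which repeats cause
   mistranslocation — and collinearity (checked with a longest-increasing-
   subsequence pass) refuses rearranged matches.
4. **Replacement planning** (`planReplacement`). The replaced focal
   interval is the span of all contigs intersecting the region between
   the two anchors — the contig(s) enclosing the fragmented gene,
   including any interior gap. The plan is demoted when the anchors are
   out of order (`skipped_inconsistent`) or when the interval overlaps
   another complete gene on the focal scaffold
   (`skipped_neighbor_conflict`): a rescue must not break a neighbor.
5. **Application** (`applyReplacements`). The donor segment between the
   flanks (the complete gene plus any inter-flank donor bases) replaces
   the interval; every base outside replaced intervals is untouched.
   Overlapping applied plans are resolved by donor score, then input
   order, with losers demoted to `skipped_inconsistent`. The report
   always conserves: cases identified = applied + skipped, by status.

### Parameter choices

* `k = 31`: odd (no reverse-complement-palindromic k-mers), long enough
  that random 31-mer collisions are negligible even at gigabase scale,
  short enough to tolerate scattered differences between assemblies of
  the same reads.
* `flankLen = 1000` bp: long enough to contain ~970 k-mers, so the 0.8
  match fraction is a meaningful vote; configurable because gene density
  and repeat content vary, and recorded in every report.
* Exact k-mer matching, no mismatches: the assemblies being reconciled
  derive from the same low-error short reads, and exactness keeps the
  anchoring re-checkable by brute-force string search.
* Both flanks must anchor. A single-flank mode would allow rescuing genes
  at contig ends but loses the bracketing guarantee; it is deliberately
  not assumed.
* Coordinates are handled in the 1-based closed convention of
  IRanges/Biostrings throughout, with BUSCO's printed 1-based inclusive
  coordinates taken as-is; a single internal convention avoids off-by-one
  drift.

## The subsampler

`sampleToCoverage` filters reads to an inclusive length window
(`minLen <= length <= maxLen`; inclusive is the least surprising reading
of a min/max specification and is documented), then draws a seeded
uniform permutation of the eligible pool and accumulates reads until
total bases reach `genomeSize * targetCoverage`. The crossing read is
included, so when the pool suffices:

```
target <= totalBases < target + maxLen
```

which makes the stop rule testable. An exhausted pool is a warning plus a
flag, not an error — partial draws are a normal outcome when subsampling
for assembler optimization. The genome size is always an explicit input;
the package never infers it, because a coverage number is meaningless
without knowing the denominator it was computed against. Multiple input
files are concatenated before filtering so the seeded permutation is over
the whole pool and independent of file boundaries. Sampling state is
private to the call: the caller's RNG is saved and restored.

## Merge diagnostics

`assessOverlap` is a *diagnostic model* of the ratio rule that gates
contig merging in hybrid assembly, not a reimplementation of any
assembler's internals: OVL is the union length of the aligned query
intervals, the aligned extent runs from the first to the last aligned
query base, n-OVL is extent minus OVL, and a pair merges iff
`OVL/n-OVL >= 1.5` (ratio infinite when n-OVL is zero). This formulation
reproduces the documented failure geometry — one distant spurious
alignment block inflates the extent, n-OVL balloons, the ratio drops
below 1.5, and the merge fails even though the real overlap is clean.
Identity and length filters (`filterAlignments`) are inclusive at their
thresholds, with the usual preset sweep 0/1000/5000/10000 bp.

`detectMergeFailureDuplicates` then explains duplicated genes in a merged
assembly. Given provenance (which input sequences each merged sequence
contains — supplied by the user or by fixture labels; this module never
runs an aligner), a duplicated gene group is `merge_failure` when one
carrier is a hybrid containing a reference sequence bearing the genes
while another carrier is an unmerged query bearing the same genes;
`preexisting` when the genes were already duplicated within one input
assembly; `unknown` otherwise. The merge-failure test is applied first:
in the failure scenario the query assembly itself often carries the gene
set twice, and the mechanistic explanation takes precedence over the
bare preexisting-duplication observation.

## Gap fates

`classifyGapFates` anchors the `flankLen = 500` bp on either side of
every pre-assembly gap in the post assembly, with the same
unique-collinear machinery as the rescue pipeline (one shared
implementation). With both anchors on one post sequence, in order:

* residual N = 0 between the anchors → `closed`;
* residual N > 0 and inter-flank span ≤ original gap →
  `partially_filled`;
* residual N > 0 and inter-flank span > original gap → `overfilled`;
* anything else (failed or multi-scaffold or disordered anchors) →
  `unresolved`.

The explicit `span > original` rule makes "the gap grew without closing"
operational; no tolerance band is applied, so a gap whose span grew by a
single base already counts as overfilled.

## What the generators emulate — and what they do not

All generators are pure functions of their arguments and seed.

* `makeToyGenome`: i.i.d. bases at a set GC fraction (default 0.42, a
  typical teleost value) with optional exact-copy repeat families. Real
  genomes have compositional heterogeneity, tandem and diverged repeats;
  exact copies are the *hardest* case for unique-k-mer anchoring, which
  is the property under test.
* `makePlantedAssemblyPair`: the focal copy splits each planted gene with
  an inserted N gap (Fragmented); the donor carries it contiguously on
  its own scaffold, reverse complemented with probability 0.5 to exercise
  orientation syncing. `repeat_flank` cases copy a gene's flank to two
  other focal positions (expected `skipped_no_anchor`);
  `orient_ambiguous` cases give the donor equal forward and
  reverse-complement halves (expected `skipped_orientation`). BUSCO
  tables are written directly from the construction — no gene predictor
  runs — so the package tests the translocation algorithms, not BUSCO.
* `makeGapFateFixture`: plants equally spaced gaps and rewrites each
  locus per its assigned fate. Truth labels are exact when flanks are
  k-mer-unique; on repeat-rich genomes, repeat-borne flanks legitimately
  classify as `unresolved`.
* `simulateLongReads`: log-normal lengths clamped to a window (a
  pragmatic stand-in for a CLR length distribution), uniform start
  positions, optional chimeras joining loci ≥ 100 kb apart or different
  scaffolds, and i.i.d. substitution errors. No homopolymer error model,
  no quality simulation, no heterozygosity.

Passing tests on these fixtures demonstrate algorithmic correctness under
controlled conditions; they do not certify behavior on diverged donor
assemblies, polyploid genomes, or error profiles the generators do not
model.

## Problem sizes and numerical notes

The package's end-to-end checks run the rescue pipeline on a 1 Mb toy
genome with 10 planted genes (6 rescuable, 2 repeat-flanked, 2
orientation-ambiguous), accounting conservation on dozens of 60 kb
fixtures, overlap assessment against a brute-force base-set union on
1,000 random block configurations, 200 planted gap fates, and sampler
uniformity over 2,000 seeded draws (chi-square goodness of fit at
α = 0.001). These sizes keep a full verification run in minutes on one
CPU while leaving every code path exercised; all of them scale linearly
if larger checks are wanted.

Degenerate inputs are defined, not accidental: an all-N scaffold is one
gap and no contigs; an empty donor list yields zero cases and an
unchanged assembly; an empty eligible read pool is an error distinct from
an exhausted one; a flank shorter than k is unusable and skips its case.
Ties in donor choice and in plan-conflict resolution are broken by score
and then input order, never arbitrarily.

## Limitations

* The rescue pipeline assumes donors assembled from the same (or very
  similar) sequence data; exact k-mer anchoring will reject flanks from
  a diverged conspecific assembly.
* The OVL/n-OVL module models a decision rule, not a merge algorithm; it
  gives the decision an auditable value, nothing more.
* Gap-fate truth requires anchorable flanks; heavily repetitive gap
  margins are reported `unresolved` rather than guessed.
* FASTQ qualities are carried through subsampling but never interpreted.
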
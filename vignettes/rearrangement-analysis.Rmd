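---
title: "Detecting repeat-mediated rearrangements in organellar genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting repeat-mediated rearrangements in organellar genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorearr)
```

## The problem

Plant organellar genomes — circular mitogenomes of roughly 100–190 kb
and plastomes around 120 kb — tend to conserve gene order between
related species. When gene order *does* differ, the standard
explanation is homologous recombination between copies of a repeated
sequence: two copies in inverted relative orientation can pair and
recombine, reversing (and strand-flipping) the segment between them.
This package provides the computational chain that turns two annotated
genome sequences into an explicit recombination hypothesis: repeat
pairs, locally collinear blocks (LCBs), a signed block permutation, and
the minimal set of repeat-mediated inversions that transforms one order
into the other. It also includes a comparative predictor of C-to-U and
U-to-C RNA editing in organellar coding sequences, since editing
analysis shares the same input data and summary machinery.

## Models and procedures

### Repeat pairs (gapless model)

A repeat pair is two genomic intervals of equal length whose sequences
match either directly or as reverse complements, with percent identity
defined gaplessly: matching columns over aligned length. Detection is
seed-and-extend. All exact k-mers (default k = 21) of the genome and of
its reverse complement are indexed — across the origin for circular
genomes — and every non-self match seeds a gapless extension in both
directions. Extension scores a match +1 and a mismatch
$-\mathrm{min\_identity}/(1-\mathrm{min\_identity})$ (so 0.90 gives
penalty 9, encoding the identity floor as a score ratio), stops when
the running score falls a fixed drop below its maximum, and the pair is
trimmed to the maximum-score span. This trim always ends on matching
columns, which is the precise form of "trailing mismatches removed";
a running-identity cutoff alone is not boundary-stable, because a
high-identity pair retains enough slack to wander far into unrelated
flanking sequence before its cumulative identity decays. Pairs shorter
than `min_len` (default 100 bp) or below `min_identity` (default 0.90,
matching the cross-genome survey threshold; the within-genome scan's
threshold is exposed as a flag because no single value is canonical),
self-matches, and near-palindromic pairs whose copies overlap by half
or more are discarded; containments on a diagonal are deduplicated.
Reported identity is rounded half-up to one decimal, with full
precision kept internally. Indel-tolerant extension is deliberately out
of scope: the gapless model keeps identity well-defined and lets a
brute-force diagonal scan act as an exact oracle in the tests.

### Collinear blocks and the signed permutation

Anchors are maximal runs of k-mers (k = `min_anchor_len`, default
25 bp) that occur exactly once in each genome, counting both strands.
Requiring uniqueness automatically excludes large repeat copies from
anchor candidacy — which is load-bearing: the block skeleton cannot be
misled by exactly the repeats whose junction placement we want to
measure. Greedy chaining joins consecutive anchors that share a
relative strand, have both coordinate gaps at most `max_gap` (5 kb),
and keep the second genome's coordinate monotone in the
strand-consistent direction. Chains spanning under `min_block` (1 kb —
kilobase-scale blocks on a 160 kb genome suppress micro-blocks thrown
off by repeat copies themselves) are dropped; survivors are labelled
A, B, C, … in reference order with boundaries at the outermost anchor
endpoints, a conservative and reproducible choice. Re-sorting blocks by
their position in the observed genome and signing each by relative
orientation yields the signed permutation. Circular inputs are
linearized at their origin rather than wrap-padded; `rotate()` moves
the origin first if it falls inside a region of interest, and the
synthetic study case keeps the origin inside the first block.

### Inversion scenarios

The block order is modelled as a linear signed permutation with the
first and last blocks effectively pinned (the flanking blocks of the
study configuration sit in the same regions in both genomes); circular
rotation equivalence is not modelled. `inversion_distance_bfs()` is a
plain breadth-first search over all reversals — exponential, guarded to
n ≤ 10, and exact, which is the point: with five blocks the state space
is trivial and the result is an oracle-grade minimal distance, not a
Hannenhalli–Pevzner approximation. The constrained search
`find_repeat_mediated_scenarios()` additionally requires, at each step,
a repeat pair with copies at the two junctions delimiting the inverted
segment, in inverted relative orientation *at that moment*. Placements
are propagated through each event: junction indices strictly inside the
span reflect; the boundary junctions — where the recombination
breakpoints themselves lie — keep their index and a mediating pair its
orientation; a pair flips orientation iff exactly one copy lies
strictly inside the span. All minimal scenarios are returned (the
two-step history is a hypothesis, not an observation, so ties must be
visible), each verified on construction to replay source into target.

Direct-orientation copies are rejected as inversion mediators:
recombination between direct copies excises the intervening segment as
a subcircle — a deletion, outside this package's scope — rather than
inverting it.

In `compare_genomes()` the placements come from the *observed* genome's
junction associations, so the constrained search runs from the observed
permutation back to the identity and the event list is reversed; since
every inversion is an involution this yields exactly the
ancestral-to-observed scenarios. The forward formulation would need
ancestral placements, which are not observable from the data.

### RNA editing prediction

The predictor translates a query CDS (standard genetic code, which
plant organelles use; the code id is a flag), aligns the translation
globally against each reference protein (BLOSUM62), and maps query
codons to reference residues column by column, skipping indel columns —
no calls are made within them, a conservative stand-in for the
published tools' undocumented internal alignments. References aligning
below a minimum identity (default 0.5, replacing an e-value cutoff that
has no meaning outside a database search) do not vote. A site is
emitted when the query residue differs from the strict-majority
consensus (ties make no call, avoiding fabricated sites) and one C↔U
substitution at a single codon position restores the consensus; when
two positions would both work, the lowest is reported. Special effects
are classified on top of the same mechanism: ACG→AUG at the first codon
(`start_gain`), an edit to a stop opposite a reference stop
(`stop_gain`), and removal of an internal stop (`orf_restoring`, also
emitted without a consensus when the single-edit repair is unambiguous).
Percentages are rounded half-up to one decimal — the convention used
throughout reported summaries — and computed from counts, never stored
independently; densities are sites per CDS base pair.

## The synthetic study case

`make_paper_case()` builds, deterministically per seed, a 160 kb
circular genome with 70 genes (mitogenome scale, GC 0.447) divided into
five 32 kb regions A–E, then:

* plants an inverted-orientation 566 bp pair with 13 mismatched columns
  (identity 97.7%) at the B|C and D|E junctions, and a
  direct-orientation 435 bp pair with 18 mismatches (95.9%) at the A|B
  and C|D junctions;
* plants eight decoy pairs of 107–380 bp in region interiors, for ten
  pairs total spanning 107–566 bp;
* applies recombination within the first pair (inverting blocks C–D,
  block order `1, 2, -4, -3, 5`) and then — the first event having
  flipped the second pair's relative orientation to inverted — within
  the second pair, giving the observed order `1, 4, -2, -3, 5`.

The ancestral placement of the second pair is a modelling choice the
data cannot fully pin down; the generator places it so that the
two-step history is feasible and records the choice in
`truth$parameters` rather than asserting it as fact.

Three generator details exist to make ground truth well-defined rather
than to flatter the detector, and are worth stating plainly:

* **Maximality by construction.** The alignment column immediately
  outside each end of a planted pair is forced to mismatch. If a flank
  column matched by chance, the *true* maximal repeat would be longer
  than the recorded one and the recorded truth would simply be wrong.
* **Interior mismatches.** Planted mismatch columns stay a seed-length
  clear of the pair ends. A near-terminal mismatch leaves the repeat
  boundary genuinely ambiguous (competing trimmings with near-equal
  identity), so no detector — including this one — could be scored
  against a sharp expected length.
* **Discoverability.** Mismatch positions are re-sampled until at least
  one clean 21 bp window survives, so every planted pair contains at
  least one exact seed at the default k.

Crossovers default to the copy midpoints (the copies' own sequence is
symmetric evidence for either side; midpoints keep both junction copies
detectable after the event), with the second breakpoint at the aligned
column of the first so that hybrid copies occupy exactly the original
intervals regardless of length parity.

What the generator does *not* emulate: real intergenic spacers are not
i.i.d. sequence (no compositional skew, no tandem microsatellites),
synthetic genes have no codon structure or introns, and no small
(< 100 bp) repeat background exists. Passing tests therefore show that
the chain of inference is correct when its assumptions hold, not that
the default thresholds are optimal for every real genome.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open internally and 1-based closed only at
the GFF3 boundary; a feature wrapping the circular origin is encoded
with `end > length` and re-normalized after rotation, avoiding split
features. Ambiguity codes are kept in sequences, excluded from GC
content, and never match in any seed, extension or identity
computation. Region statistics are always computed from annotations
rather than transcribed from external tables (printed region lengths in
published summaries do not always sum to the stated totals). A
zero-site editing summary reports undefined percentages, not 0/0.
Scenario search distinguishes "no scenario within the event bound"
(empty list) from errors; the BFS reports not-found as `NA`, never a
truncated count. Ties among overlapping repeat candidates resolve by
maximal length, then maximal identity, then smallest start.

## Problem sizes used in the tests

The shipped suite exercises the full 160 kb study case once (shared
across test files), ten 40 kb single-inversion reconstructions, twenty
50 kb empty-genome scans, and brute-force oracles on 1.2–4 kb
sequences, where exhaustive diagonal scans and full state-space
shortest paths are cheap. These sizes were chosen so that every
property has an independently computed expected answer; the pipeline
itself has no size limit beyond memory, and the defaults reproduce the
study-scale analysis directly.

## Known limitations

* Gapless repeats only: an indel inside a repeat splits it into two
  reported pairs.
* Pairwise comparison only; no multi-genome alignment, no
  translocation/transposition/DCJ models, and no circular rotation
  equivalence in the permutation model.
* Repeat families with more than two copies are reported as all
  qualifying pairs, not clustered.
* The editing predictor is comparative: it cannot find sites absent
  from all references, and it does not reproduce any specific published
  site list, which would require that tool's reference database.
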
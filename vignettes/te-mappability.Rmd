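---
title: "Scoring TE mappability with single-end and paired-end libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring TE mappability with single-end and paired-end libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temap)
```

## The quantity being computed

Reads from transposable elements (TEs) are hard to assign to a locus because
recently active subfamilies (L1HS, AluY and their relatives) exist as many
near-identical copies.  `temap` quantifies this with a *mappability score*
per genome position: the reciprocal of the number of placements at which the
read (or read pair) originating at that position aligns within a mismatch
allowance.  A score of 1 means the read maps back only to its origin; 1/5
means an aligner reporting all alignments would return five candidate
placements.  Scores are attributed to the forward-strand start coordinate of
the read or fragment.

Alignment is gapless: a placement is any (position, strand) whose window is
within Hamming distance `m` of the read, on either strand.  This matches the
`-v`-style behaviour of short-read aligners run in all-alignments mode and
keeps the simulation model exact (the synthetic-genome generator introduces
substitutions only, so planted truth is recovered bit-exactly).  Windows
containing N never match, and positions whose own window contains N or runs
off the chromosome are *undefined* (NA), not zero: a simulated read set
never contains those reads, so they carry no evidence either way.

### Two calculation routes

Two routes to the same quantity are implemented because each validates the
other:

* **Method 1** builds a table of exact occurrence counts for every k-mer
  present in the genome (counting (position, strand) placements, so the
  table is closed under reverse complement) and, at each position, sums the
  counts of the distinct library k-mers that align there in forward
  orientation.
* **Method 2** counts all placements of the position's own read or pair.

For single-end libraries the two are *exactly* equivalent, and the test
suite asserts bit-identical tracks on random genomes.  The equivalence is a
small theorem: every placement of the focal read corresponds one-to-one to
an exact placement of some neighborhood k-mer, provided the count table is
closed under reverse complement and method 1 restricts the summed k-mers to
forward-orientation alignments at the focal position.  We adopt both
conventions package-wide — including for paired-end scoring, where the same
restriction is what makes n identical planted copies score exactly 1/n
under both methods.  For paired-end libraries the routes are no longer
identical (method 1 aggregates fragment-level counts anchored at the focal
start; method 2 re-aligns the focal pair), and the package reports rather
than hides their disagreement rate on fixtures.

### Paired-end semantics

A fragment of length `L` starting at `p` yields `read1 = genome[p, p+r)` and
`read2 = revcomp(genome[p+L-r, p+L))` — a forward-reverse library with the
interior gap discarded (for the 76 bp / 242 bp library the discarded gap is
90 bp).  A paired placement requires both mates within the per-read mismatch
allowance, in FR orientation, with implied fragment length inside
`[insert_min, insert_max]`.  Placements differing only in insert size are
counted as *distinct* mappings.  This is deliberately conservative: in
tandemly repeated sequence a pair can re-align at its own start position
with several insert sizes, which can push paired-end scores *below*
single-end scores at the same position.  The test suite constructs a
period-10 tandem array exhibiting exactly this effect and shows it
disappears when the insert range is pinned to `[L, L]`.

The insert range default is `[max(2r, L - 50), L + 50]`.  The tools this
emulates accept a spread of insert sizes around the library median rather
than a fixed value, but no single canonical range exists for fragments of
200–300 bp; a symmetric ±50 bp slack is the package's documented default and
is configurable in `map_params()`.

### Engine and oracle

The engine uses a pigeonhole seed index internally (any alignment with at
most `m` mismatches contains an exact match of one of `m+1` disjoint seeds)
but is contractually exhaustive.  Correctness is anchored by
`oracle_score()`, a naive full scan with no index or shortcut, implemented
separately from the engine; tests compare the two at every position of mixed
fixtures (repeats, tandems, N patches) in both modes and both methods.

## Locus aggregation

A TE locus is *uniquely mappable* only if every defined start position
inside it scores exactly 1; a single multi-mapping position disqualifies the
locus.  The per-locus *percent unique* is the percentage of defined start
positions scoring 1.  Undefined positions are excluded from numerator and
denominator.  Start positions near the 3' boundary whose reads extend into
the flank are included — the all-positions-unique rule prevents unique
flanks from inflating the call, and the tests verify that extending a locus
into unique flank can raise percent-unique but never flip `is_unique` from
false to true.

Summaries roll up to subfamily, family and class with two statistics:
percent of loci uniquely mappable, and the mean per-locus percent unique.
Library comparisons subtract per-locus percent-unique between score sets;
for fairness the comparison filter drops loci where every paired-end library
is already saturated at 100% and loci shorter than 300 bp (the span of the
longest fragment library).

## The synthetic-genome generator

Real reference genomes and RepeatMasker annotations are too large for
routine verification, and provide no ground truth.  The generator plants
what drives TE mappability:

* **copy number** — more identical copies mean lower scores (n exact copies
  with `m = 0` score exactly 1/n inside the copies, the package's sharpest
  recovery test);
* **divergence** (`sub_rate`, an age proxy) — i.i.d. substitutions make
  copies mutually distinguishable, so percent-unique rises with rate; the
  tests assert the trend over rates 0 / 0.05 / 0.15;
* **5' truncation** — L1-style insertion copies a 3' suffix; truncation
  fractions are drawn per copy, and truth maps record each copy position's
  consensus coordinate;
* **segmental duplications** — a verbatim copy of a finished region is
  appended after TE planting, giving duplicated loci fresh ids and dropping
  the originals below 100% unique however diverged they are.

Copies are placed uniformly without overlap (overwriting background, so
coordinates never shift), and everything is reproducible from one seed.
What the generator does *not* emulate: insertion-site preference, target
site duplications, indels, transduction, and population polymorphism.
Passing tests therefore demonstrate correctness of the scoring machinery
and the direction of copy-number/age/read-length effects, not quantitative
agreement with any real genome.

## Statistical analyses

`permutation_test()` compares mean percent-unique between two groups of
loci with a two-sided label-shuffling test.  Sampled mode uses the add-one
rule `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`, so p is never 0 and
never below `1/(n_perm + 1)`; when `choose(n, n_a)` is small the test
switches to exhaustive enumeration and the p-value is exact.  Reported
p-values from sampled runs are therefore floored — a printed p like 2.2e-16
from other software is a numeric floor, not an attainable permutation
p-value, and this package does not produce such values.

`consensus_profile()` maps each locus onto its subfamily consensus and
pools, per consensus position, the scores of the locus positions mapped
there (median and quartiles with linear interpolation, plus coverage
depth).  Mapping uses either simulator truth maps or the built-in
semi-global aligner: the locus is aligned end-to-end, consensus overhangs
are free (so 5'-truncated copies align to a suffix at no cost), scoring
match +1, mismatch −1, and affine gaps costing `-5 - g` for a gap of length
g.  Tie-breaks are deterministic (highest score, then leftmost consensus
end, substitutions preferred over gaps).  On the generator's indel-free
copies the aligner recovers truth maps exactly, which is the regime the
package guarantees; on heavily indeled real loci a dedicated aligner may
differ.  `classify_subclade()` reads the locus bases mapped to diagnostic
consensus positions (for human L1HS, the 3' UTR trinucleotide: ACA for Ta,
ACG for preTa) and labels the locus, returning `"unclassified"` when the
site is truncated away or gapped; the diagnostic coordinates are user
input, as they are defined in the subfamily literature, not by this
package.

## The demo pipeline

`run_demo()` chains everything at desk scale: an 80 kb background with a
young (sub_rate 0.01) and an old (0.12) L1-like subfamily (6 copies each,
5'-truncated), a 20-copy Alu-like SINE, and one segmental duplication; six
tracks (single-end 50/76/100 bp and paired-end 50/76/100 bp with fragments
200/242/300 bp, 3 mismatches); locus tables, subfamily summaries, library
comparisons, a young-vs-old permutation test and a consensus profile.  A
single global seed is fanned out to stage seeds by fixed offsets, and
re-running with the same seed reproduces every output byte-identically.
These problem sizes keep the full pipeline at a few seconds on one core
while still exercising every code path; all sizes scale up linearly via
`sim_config()`.

```{r demo, eval = FALSE}
res <- run_demo(out_dir = "demo_out", seed = 1)
res$summaries$subfamily
res$permtest
```

## Numerical and format notes

* Every defined score is the reciprocal of a positive integer; tests check
  this invariant directly.
* Tracks are written as bedGraph (0-based half-open, run-length encoded) or
  fixedStep wiggle (1-based), with 17 significant digits so a write/read
  round trip reproduces scores bit-exactly.
* Internal coordinates are 0-based half-open everywhere; conversions happen
  only at parse/serialize boundaries (RepeatMasker `.out` rows are 1-based
  inclusive; wiggle is 1-based).
* RepeatMasker rows flagged `*` (overlapping a higher-scoring match) are
  kept by default and can be dropped with `drop_overlapping = TRUE`; nested
  or fragmented elements sharing a repeat id are scored as independent
  rows.
* Palindromic windows count as two placements (one per strand), matching an
  aligner that reports (position, strand) pairs.
* The mismatch allowance applies per mate, not jointly, in paired mode.
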
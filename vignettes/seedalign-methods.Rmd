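---
title: "Methods: block-parallel banded alignment and the bucket-hash seed index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-parallel banded alignment and the bucket-hash seed index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedalign)
```

## The problem and the model

Short-read mapping asks, for each read of at most 100 bp, where in a
reference genome it aligns with a bounded number of errors. `seedalign`
follows the seed-and-extend strategy: exact 15 bp matches (seeds)
nominate candidate windows, and a banded semi-global Needleman–Wunsch
verifies them. The scoring model is deliberately minimal — unit costs
(match 0, mismatch 1, indel 1), no base qualities, no affine gaps — and
the band half-width is fixed at $d = 1$, so an alignment can contain at
most one net indel. A read of length $L$ is accepted when its score is
at most $\lfloor L (1 - 0.9) \rfloor$ (90% identity); together with the
band this realises the "many substitutions, at most one indel" error
regime typical of Illumina-style data.

The semi-global convention deserves care, because the package computes
the same quantity by two different routes and they must agree exactly.
Within a candidate window:

* leading *read* gaps are charged ($S(0,j) = j$),
* leading *reference* gaps are charged ($S(i,0) = i$ inside the band),
* trailing reference bases are free — the result is the minimum over
  the last DP column across the band diagonals.

Charging the leading reference gap is a design choice with a reason: a
window is a diagonal hypothesis made by a seed, so an alignment that
truly starts one base to the left of the window is evidence for a
*different* diagonal. Rather than silently absorbing it with a free
gap, the extension stage runs a second engine on the window shifted one
base left and keeps the better result; symmetrically, the lower
diagonal of the last column is scored against the one extra base to the
right of the window (an absent base counts as a mismatch, so a clipped
window can never produce an optimistic score). This dual-engine
construction recovers exactly the boundary cases a single windowed
engine gets wrong, without ever fabricating sequence.

## The block decomposition

The banded DP has a three-cell column state: the upper, main and lower
diagonal of the band. The engine partitions read columns into an
initial segment (the 4 bp "head" in the default geometry) followed by
8 bp blocks, and summarises each block by the triple
$(S_u, S_m, S_l)$ of best within-block path costs per exit diagonal,
each annotated with the *entry* diagonals that achieve it. Scores above
the acceptance threshold are pruned to `×` (represented as `Inf`,
absorbing under addition, ignored by `min`); because every DP increment
is non-negative, intermediate pruning can never alter a surviving
score.

Two concatenation modes combine blocks:

* **heuristic** — one label-annotated triple per block, chained by
  adding the predecessor score of a labelled entry diagonal (ties keep
  all labels). This is the summary a fixed-function parallel pipeline
  would keep per block. Every chained score is the cost of a realizable
  banded path, so the heuristic can over-score but never under-score
  the optimum; a parallel implementation would concatenate with a
  balanced tree while this one folds left-to-right, which preserves the
  same guarantee.
* **exact** (default) — each block contributes its full $3 \times 3$
  transfer table $T[e, x]$ (best entry-to-exit cost), composed under
  min-plus. Min-plus composition is associative (property-tested in
  any association order), and composing all tables against the initial
  segment's exit vector reproduces the banded DP *exactly*; the test
  suite verifies the identity exhaustively on a two-letter alphabet up
  to length 8 and on random ACGT pairs up to 96 bp.

The decomposition exists for parallelism: in the cost model,
a sequential banded DP needs one step per read column, while the block
form needs `block_width` steps for all blocks in parallel plus a
$\lceil \log_2 n_{blocks} \rceil$-deep concatenation tree
(`estimate_cycles(12, 4, "parallel")` = 6 versus 12 sequential). The R
implementation keeps the algebra (`block_score`,
`concatenate_blocks`, `finalize_score`) as first-class objects so the
worked three-block example and the pruning behaviour can be inspected
directly.

## The seed index

A 15 bp seed packs into 30 bits (base-4 positional expansion, A=0, C=1,
G=2, T=3 — chosen so complementation is `XOR 3` and reverse
complementation is branch-free). The top 16 bits select a bucket, and
the 14-bit suffix is hashed to 12 bits by a per-bucket H3 function: the
XOR of rows of a random binary matrix selected by the suffix's set
bits. H3 functions are linear (`h(a XOR b) = h(a) XOR h(b)`), cheap,
and bucket-local, so collisions are confined within a bucket. The
primary address space is $2^{28}$ slots; only occupied slots are stored
(a sparse map with semantics identical to the dense layout, which would
cost 1 GB), and the serialization writes the dense block only for small
configured geometries (≤ $2^{22}$ slots). Slots with a single position
store it inline; slots with several positions (a repeated 15-mer, or
two distinct seeds colliding in a bucket) move all positions to a
collision table. The slot does not record which seed a position belongs
to — false candidates from shared slots are eliminated by the extension
stage, never by the index. The 7-bit count field caps a slot at 127
stored positions; overflowing slots keep their first 127 positions and
are reported on the index object.

Seeds are taken at every read offset by default (`stride = 1`, plus
always the final offset so the 3′ end is covered); the stride is
exposed because sparser seeding trades sensitivity for speed. Hits are
merged per (strand, diagonal) before extension, since duplicate seeds
on one diagonal would repeat identical work.

## Paired-end model

Mates are FR-oriented; the outer distance (leftmost base of the left
mate to rightmost base of the right mate) is modelled as
Normal($D$, $\sigma$), $D = 200$, $\sigma = 20$ by default. The window
multiplier $k = 3$ accepts ~99.7% of true inserts. Rescue of an
unmapped mate searches the window the model predicts (length about
$2k\sigma$ plus the read length) with full-matrix Smith–Waterman under
unit scores (+1/−1/−1), in both orientations, and accepts a placement
only when at least 90% of the read's bases match on the optimal local
path — unit scores keep that cutoff interpretable. $k$, the SW scores
and the identity floor are configuration, not constants, because the
original design fixes none of them.

## The simulator, and what passing tests do and do not show

The generator emulates wgsim-style sampling: uniform start positions
and strands, i.i.d. substitutions at the configured rate, FR pairs with
rounded-normal outer distances, and **at most one 1-bp indel per read**
(default `indel_prob = 0.10`). The single-indel simplification is
deliberate: the $d = 1$ band makes multi-indel reads unalignable by
design, so simulating them would only measure the simulator. Truth
travels in a TSV sidecar; a parser for wgsim's name-encoded convention
covers real wgsim output.

The simulator does *not* emulate sequencer error profiles (quality
decay along the read, indel homopolymer bias), genome repeat structure,
or coverage biases. Passing the synthetic recovery tests therefore
shows the pipeline is correct and sensitive under its stated error
model on a non-repetitive genome; it does not predict mapping rates on
real data, where repeats create genuinely ambiguous placements and
error processes are structured.

Evaluation uses the ±5 bp rule: an aligned read is correct when the
strand matches and the best reported position is within 5 bases of
truth. With multiple reported hits the best (minimum score, leftmost on
ties) is judged.

## Numerical and degenerate-input choices

* `×` is `Inf` throughout; the compiled kernels use a large integer
  sentinel with guarded addition.
* `error_threshold` computes $\lfloor L(1 - \text{identity}) + 10^{-6}
  \rfloor$; the epsilon guards against binary-fraction artefacts (e.g.
  $100 \times (1 - 0.9)$ evaluating just below 10).
* Windows are clamped at genome boundaries and never padded; missing
  context is charged as gaps or mismatches. At `window_start = 0` the
  shifted engine simply runs on the one-base-shorter window.
* Reads shorter than the seed length produce no candidates (warned);
  reads longer than `max_read_len` are rejected unless 3′ trimming is
  requested.
* Ties in block-score start labels keep *all* minimizing entry
  diagonals, making the heuristic as tight as its label scheme allows.
* All randomness (N resolution, H3 matrices, simulation) flows through
  explicit integer seeds and restores the caller's RNG state.

## Problem sizes used in the checks

The exactness sweep covers all $\sum_{L\le8} 2^L \times 2^L = 87{,}380$
two-letter read/window pairs plus 1,000 random ACGT pairs of lengths
8–96; the synthetic recovery runs 10,000 simulated 76 bp reads against
a 100 kb random genome at 0% error (sensitivity and accuracy must both
be 1.0) and at 4% substitutions with the one-indel model (sensitivity
≥ 0.95 expected: the binomial tail above the 7-error threshold plus
seed destruction accounts for the ~2% loss). These sizes exercise every
code path — chunking, both strands, collision slots, dual-engine
boundary cases — while keeping the whole suite inside a half-minute.

## Known limitations

* Genomes are limited to $2^{24}$ bases by the 24-bit position fields;
  larger references need wider fields (config) or partitioning.
* No traceback/CIGAR: the engine reports positions and scores (SAM
  CIGAR is `<len>M` with the edit cost in `NM`), matching a design that
  reports hits, not base-level alignments.
* Band width beyond 1 is supported only by the reference DP, not the
  block engine (whose state is the three diagonals).
* One reference sequence per index; multi-chromosome references would
  need an id-partitioned position space.
* MAPQ is not modelled (reported as 255); multi-mapping reads are
  reported in full (or best-only with a flag) without a mapping-quality
  calculus.
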
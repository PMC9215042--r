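---
title: "Repeat resolution with read-length k-mers: methods notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat resolution with read-length k-mers: methods notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the model kresolve implements, the parameters that
matter, the numerical and design choices made where the design was open,
and what the synthetic-data tests do and do not establish. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Model

A unitig graph built at `k_assembly` collapses every genomic repeat of
length at least `k_assembly - 1` into one node. kresolve revisits such
junctions with a single larger k-mer size `k_big` without rebuilding the
graph. The reads are indexed once per library: the `t` consecutive
`k_big`-sized k-mers anchored at the 5' end of each read are inserted
into a Bloom filter (canonically hashed, so both strands are one
element). Anchoring at the 5' end sidesteps the quality drop at the 3'
end of short reads; storing exactly `t` k-mers per read makes one read
found along a path sufficient for support while keeping the filter load,
and hence its false positive rate, low.

For each repeat node with at least two in- and two out-neighbours, every
`(in, out)` pairing is a candidate path. A `k_big` window slides along
the spelled path in 1 bp steps; each position is one membership test.
The decision is binary: a path reaching `t` hits is supported. Support
is evaluated against local coverage:

* reads on the path: `R_p = sum(cov_sum) / (l - k_assembly + 1)`, since
  a read of length `l` contributes `l - k_assembly + 1` assembly k-mers
  to the multiplicity sums the assembler stores per unitig;
* expected spacing between read 5' ends: `s = (L - l + 1) / R_p` for a
  path of spelled length `L`;
* required window moves: `tests = ceil(max(m, s * f + t))`.

The floor `m` protects correct paths from being tested too little; the
factor `f` absorbs the coarseness of contig-level coverage estimates. A
window overlapping all three nodes by at least `margin` bases can start
at `k_big - L_repeat - 2 * margin + 1` distinct positions at most, so a
repeat is evaluable only when
`L_repeat <= k_big - (tests - 1) - 2 * margin`. If `tests` exceeds the
cap `M`, or positions run out, or the path has zero coverage, the path
draws a skip verdict - and one skipped path skips the whole repeat. A
repeat resolved from partial information risks a misassembly, so partial
information is never acted on; this is also why, at very low coverage,
the algorithm's main output is the *absence* of edits.

When the flanking nodes are shorter than the window's reach
(`k_big - L_repeat - margin` per side), the flanks are expanded
breadth-first through their own neighbours until each branch supplies
the needed bases or dead-ends, capped at `max_side_paths` per side;
left x right extensions form combination paths, subsampled uniformly to
`max_combinations`. Support of any combination supports the original
three-node path.

Resolution reads the support matrix as a bipartite graph over
in/out-neighbours. Each connected component of supported pairs receives
its own copy of the repeat node (equal split of the multiplicity sum); a
1-to-1 component merges into plain linear sequence, a larger component
leaves a smaller repeat (partial simplification). A neighbour with no
supported partner loses its link only if something else at the site is
supported - an entirely unsupported site is left untouched rather than
stranding true sequence on index misses. Two evaluation/resolution
passes run per library (the second pass picks up sites uncovered by the
first), libraries in ascending read-length order, each with its own
`k_big` and index.

## Parameters

| name | default | unit | role |
|------|---------|------|------|
| `t` | 4 | hits / k-mers | support threshold; k-mers stored per read |
| `m` | 18 | tests | minimum window moves per path |
| `M` | 40 | tests | maximum; beyond it the repeat is skipped |
| `f` | 4 | - | spacing correction factor in `s * f + t` |
| `margin` | 2 | bp | minimum window overlap on adjacent nodes |
| `h` | 7 | - | Bloom hash functions |
| `max_side_paths` | 75 | paths | flank extensions per side |
| `max_combinations` | 5625 | paths | `max_side_paths^2`, subsample beyond |
| `iterations` | 2 | passes | evaluation/resolution rounds per library |
| `k_big` | `k_assembly + 60`, capped at `l - t + 1` | bp | window size |
| `bloom_bits` | `2^29` (64 MiB) | bits | filter size; FPR is reported, not targeted |

The `k_big` default follows the empirical observation that an offset of
+60 over `k_assembly` balances contiguity gain against misassemblies;
the cap guarantees each read still yields `t` k-mers.

## Numerical and design choices

These are the package's own decisions where the method description left
the detail open; each is covered by a test.

* **Rounding of `tests`.** `s * f + t` is real-valued; we round up after
  the max. Rounding down could make the final stored k-mer of a read
  unreachable in edge cases; up is conservative.
* **`L < l` paths.** When the spelled path is shorter than a read, the
  spacing formula turns negative; we set `s = 0` (dense-coverage limit).
  The `m` floor still governs, so such paths are tested 18 times.
* **Which windows.** The window moves are the first `tests` valid start
  positions from the left. The description counts consecutive positions
  in its eligibility bound, and a deterministic rule is required for
  reproducibility; testing all valid positions would be a (noisier,
  slower) alternative.
* **Hits are positions, not distinct k-mers.** Identical k-mers at two
  window positions count twice. At `k_big` near read length, repeated
  window k-mers within one path are rare.
* **Canonical hashing.** The rolling hash maintains forward and
  reverse-complement polynomial hashes (odd 64-bit multiplier, mod
  2^64) and takes their minimum, then derives `h` bit positions by
  double hashing. This keeps O(1) updates per step; taking the
  lexicographically smaller *string* first would force O(k) work per
  position. Where strings are the natural currency (k-mer counting, the
  exact-set oracle index) the lexicographic-min canonical string is
  used. Only membership behaviour matters: the test suite pins zero
  false negatives, strand symmetry, agreement of rolling with
  per-window recomputation, and identity of support matrices under the
  Bloom filter versus an exact k-mer set at negligible FPR.
* **Partial simplification.** Splitting by connected components of the
  support graph reproduces the intended outcome - fewer traversable
  `(in, out)` pairs, never more - without assuming any particular
  matching inside an ambiguous component.
* **Multiplicity of copies.** The duplicated repeat's `cov_sum` is an
  equal split of the original, conserving the total; the true
  per-copy coverage is unknowable at this stage.
* **Conflicting edits.** Two sites sharing a node are serialized: the
  second edit is deferred to the next pass rather than solved jointly.
* **Degenerate nodes.** Palindromic nodes and nodes with self-loops are
  never merge candidates and never repeat sites; their strand geometry
  is ill-defined for the three-node path model.
* **Zero-coverage and non-ACGT.** `R_p = 0` is a skip verdict, not an
  error; a spelled window containing non-ACGT cannot be hashed and
  counts as a miss.

## The synthetic world

`make_repeat_genome()` builds `U0 R U1 R U2 ...`: unique segments
alternating with exact repeat copies, rejection-sampled so that unique
segments share no `k_assembly`-mer with each other or the repeats - the
truth table of junctions is therefore exact. `simulate_reads()` draws
single-end reads uniformly from both strands (pairing is unused by the
algorithm) with i.i.d. substitution errors. `build_unitig_graph()`
counts canonical k-mers, filters by multiplicity (`kc_min`), and
compacts chains - a faithful, small-scale stand-in for an assembler's
DBG stage, checked against a brute-force decomposition of the genome
string itself.

Defaults state the world the tests run in: 5 kb unique flanks, one 80 bp
repeat x 2 copies, `k_assembly = 51`, error-free 151 bp reads at 40x,
`k_big = 111`. Two behaviours of real data emerge even here and are
asserted as such rather than idealized away: the unitig graph built from
reads is truncated by a few bases at the genome ends (terminal k-mers
are covered only by reads anchored exactly there), and the repeat unitig
extends past the nominal repeat length whenever the flanking copies
happen to share boundary bases (coincident junction k-mers).

What the simulator does **not** emulate: coverage biases (GC,
mappability), indels and structured error profiles, quality strings,
tandem repeats and nested repeat families, diploidy, and real assembler
idiosyncrasies (tip clipping, bubble popping, average- rather than
sum-based coverage tags). A green test therefore establishes algorithmic
correctness on clean interspersed repeats - supported paths are exactly
the genomic ones, skipping triggers under thin coverage, resolution
reconstructs the planted genome - not performance on real libraries.

## Known limitations

* Coverage estimation is contig-level; long nodes with uneven coverage
  bias `R_p` in the direction of fewer tests, which the `f` factor only
  partially compensates.
* Read errors inside the first `k_big + t - 1` bases of a read suppress
  its index k-mers entirely (reads are indexed whole or not at all); at
  high error rates correct paths lose support before chimeric ones gain
  any, so the failure mode is conservative (fewer edits).
* Repeats longer than `k_big - (m - 1) - 2 * margin` bases
  (90 bp at the defaults with `k_big = 111`) are out of reach by
  construction; the remedy is longer reads, not more tests.
* The resolver never cuts sequence; mistakes it can introduce are
  limited to wrong duplications/merges at evaluated sites, which the
  skip rules are designed to make rare at the cost of leaving
  low-coverage repeats unresolved.
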
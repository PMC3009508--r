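---
title: "The gap-matrix recursion system: model, execution strategies, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gap-matrix recursion system: model, execution strategies, and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotfold)
```

## The problem and the scoring model

An RNA sequence folds back on itself; the resulting set of base pairs is its
secondary structure. Pseudoknots — crossing pairs, where residues inside one
helix's loop pair with residues outside it — matter biologically but break
the nested-interval decomposition that makes classic structure prediction an
O(n³) dynamic program.

`knotfold` scores structures by **base-pair maximization**: each admissible
pair contributes a fixed positive weight and the optimum maximizes the total.
A pair `(i, j)` is admissible when its base class is allowed (`AU`, `GC` and
the `GU` wobble by default; configurable with per-class weights) and when
`j − i > h` with `h = 3` by default, so a hairpin loop keeps at least three
unpaired residues. Forbidden pairs carry the score `-Inf`, which is absorbing
under addition and can never win a maximization. This scoring intentionally
replaces thermodynamic energy tables: the combinatorial structure of the
recursion system — which is what this package studies — is unchanged, while
every score becomes exactly checkable against enumeration.

## The matrix system

Two triangular tables cover nested structure: `vx(i, j)` is the best score of
`[i, j]` under the assertion that `(i, j)` itself pairs, and `wx(i, j)` the
best with no assertion. `vx` must be computed before `wx` at each cell, and
cells are filled over subintervals of increasing length.

Crossing configurations are reached through the **one-hole gap matrix**
`whx(i, j : k, l)`: the best score of the two-segment region
`[i, k] ∪ [l, j]`, whose hole `[k+1, l−1]` is deliberately left unfilled so
that an interleaving partner piece can occupy it. Boundary conventions close
the system: an empty left segment (`k = i−1`) reduces to `wx(l, j)`, an empty
right segment (`l = j+1`) to `wx(i, k)`, both to 0, and an empty hole
(`l = k+1`) to `wx(i, j)`.

Three derived quantities — the closures — assert pairs at the region's ends:
`zhx` pairs the outer ends `(i, j)`, `yhx` pairs the hole flanks `(k, l)`
across the hole, `vhx` pairs both. Under max-pairs scoring they are thin,
single-addition functions of `whx`, so this package evaluates them on demand
per cell rather than storing three more Θ(n⁴) tables; they remain first-class
families for auditing and profiling. For the same reason the auxiliary
matrices that a thermodynamic implementation keeps alongside `wx` and `vx`
collapse to documented aliases here (the `wx` table itself, and the paired
interior term of `vx`), with no separate storage.

One non-obvious constraint deserves a note: `vhx` asserts two pairs, `(i, j)`
and `(k, l)`, which requires four distinct positions, i.e. `k > i` and
`l < j`. Without that condition the degenerate cells whose hole flanks
coincide with their outer ends (such as `whx(i, j : i, j)`) would count one
physical pair twice and the optimum would exceed the matching bound
`floor(n/2)`; the constraint is enforced in the fill, the traceback, and the
grammar oracle alike.

The `whx` recursion splits into six mutually independent **work blocks**:

* **B1** (loop-free): four trims — shrink the outer span from either end or
  grow the hole from either side, each meaning one residue goes unpaired —
  plus the three closures;
* **B2/B3**: split the left segment at `r`, pairing a `wx` region with a
  smaller gapped region (`wx(i,r) + whx(r+1,j:k,l)` and the mirror with
  `wx(r+1,k)`);
* **B4/B5**: the same for the right segment;
* **B6** (gap-gap): split the region into *two* gapped pieces,
  `whx(i,j:r−1,s+1) + whx(r,s:k,l)`, with the identity split `(r,s) = (i,j)`
  excluded. This block is what raises the fill from O(n⁵) to O(n⁶) time; it
  can be disabled (`dp_options(gap_gap = FALSE)`), restricting the reachable
  structure class but keeping everything else intact.

Finally, the pseudoknot composition feeding `wx` takes two interleaving
gapped pieces, `whx(i,c:a,b) + whx(a+1,j:b−1,c+1)`: piece one occupies
`[i,a] ∪ [b,c]`, piece two `[a+1,b−1] ∪ [c+1,j]`, each filling exactly the
other's hole. In the H-type witness G⁴A⁴C⁴U⁴ the split `a=4, b=9, c=12`
(1-based) yields two four-pair helices and the analytic maximum n/2 = 8.

## Fill order and the dependency audit

Cells are filled by outer span `d = j − i` ascending; within one `(i, j)`,
gap cells go by hole size *descending*, because B1's hole-growing trims, the
closures, and B6's outer factor all reference larger holes at the same
`(i, j)`, while every other reference has a strictly smaller outer span. The
pseudoknot composition reads only smaller spans, so `wx(i, j)` is computed
last in its cell.

This ordering is not taken on faith: with `dp_options(audit = TRUE)` the fill
logs every table access in order and `audit_log()` exposes the trail. Tests
assert (i) zero read-before-write violations, (ii) that the observed
family-to-family reads form a subset of the sanctioned dependency ledger
(after the alias collapse above), and (iii) the non-serial polyadic
character: gap-cell evaluations read cells whose outer span is smaller by two
or more, not just the previous diagonal.

All coordinates are 1-based inclusive throughout the package (R's native
convention); CT files are 1-based by definition and dot-bracket strings are
index-free.

## Execution engines

Because max is associative and commutative, and because the six blocks of a
cell share no data dependency, *who* evaluates the blocks cannot change the
result. The engines exploit that freedom in three ways, mirroring code
parallelism (each block offloaded whole, `engine_cpar()`), data parallelism
(all loop iterations flattened and chunked evenly, `engine_dpar()`, with
tasks grouped per cell), and a hybrid (`engine_hpar()`), where a threshold
scheduler engages the persistent worker pool only when a cell offers at
least `min_iters = 5` iterations to each of at least `min_workers = 2`
workers; 6 workers and 30 iterations is full utilization. The threshold is
applied to the cell's total loop-iteration count — the quantity the
scheduling parameters are stated in — rather than to sequence length, so
short sequences go almost entirely to the coordinator and the serial/parallel
split per run is exactly reproducible (`sched_summary()`).

Workers are persistent in-process entities exchanging task/reply messages:
started before the first cell, dismissed by an explicit shutdown message,
reusable across cells. Two payload modes exist because every loop block
reduces to max over an elementwise sum of two stored value vectors: under
`"snapshot"` (default) a task carries index ranges against a read-only view
of the tables; under `"package"` the coordinator ships the candidate values
themselves and workers never touch the tables. Both are tested to produce
identical tables. Real OS-level parallelism is deliberately out of scope:
the engines' contract is result equivalence and scheduling behavior, both of
which are exact and deterministic in-process, whereas forked execution would
add nondeterministic overhead and no additional scientific content.

The traceback never depends on the engine: it replays the recursions from
`wx(1, n)` taking the first matching alternative in a fixed order (`vx`,
left trim, right trim, bifurcation by ascending split, pseudoknot by
ascending `(a, b, c)`; within `whx`: B1 in listed order, then B2–B6 by
ascending loop index). Replayed candidates are recomputed with the same
arithmetic as the fill, so exact floating-point equality identifies the
winning alternative.

## Profiling

`profile_run()` counts, per matrix family, the number of cells and the number
of elementary operations — candidate values entering a maximization, with
each closure evaluation counted once to its own family. The counts are a
deterministic function of `(n, options)` (every candidate is evaluated
whether or not it wins), which makes the profile a reproducible surrogate
for wall-clock attribution: WHX has Θ(n⁴) cells with up to Θ(n²) work each,
against Θ(n²) cells elsewhere, so its share strictly dominates from small n
onward and grows with n (`share_trend()`). Wall times are also reported per
family but are informative only; no test or acceptance quantity depends on
them, since timing shares are hardware-bound while operation shares are not.

## Verification oracles

Three independent authorities live in the package (not only in the tests),
behind the `verify` subcommand:

* `nussinov_max_pairs()` — the classic O(n³) nested-only maximization,
  sharing no code with the gap-matrix fill; the DP with pseudoknots disabled
  must equal it on every input.
* `enumerate_grammar_max()` — an exhaustive top-down evaluation of the same
  recursion rules with scalar loops and a per-cell cache, no code shared
  with the table fill. A cache-free derivation-tree expansion of this
  grammar is astronomically infeasible even at n = 10 (the B1 alternatives
  alone branch four ways over a span-plus-hole potential of ~2n), so the
  oracle's independence rests on its different traversal and code path, plus
  the two other authorities; it is capped at n ≤ 12.
* `max_matching_upper_bound()` — brute-force maximum disjoint pairing with
  the min-loop rule and *no* topological restriction (n ≤ 14): an upper
  bound on anything the grammar can build, and ≤ floor(n/2) under unit
  weights.

The chain `nussinov ≤ grammar ≤ matching bound` is itself asserted on random
sequences.

## Synthetic data

The generator (`fixture_sequences()`) produces the three input families the
test suite and acceptance run are built on: uniform random A/C/G/U sequences
(no structural signal — the right substrate for oracle agreement and
property checks), hairpins `G^m A^4 C^m` with a forced nested optimum of m,
and H-type pseudoknots `G^m A^m C^m U^m` whose optimum is the 2m interleaved
pairs. Random draws are seeded and leave the caller's RNG state untouched.
What these fixtures do **not** emulate: base composition bias, naturally
occurring structural motifs (bulges, multiloops under energy models),
modified bases, or experimentally validated pseudoknot families. Passing
tests therefore demonstrate algorithmic correctness of the recursion system
under max-pairs scoring, not predictive accuracy on biological RNA — the
latter would require a thermodynamic parameterization, which is explicitly a
non-goal.

## Problem sizes and numerical choices

The fill is Θ(n⁶) time and Θ(n⁴) space with B6 on; a guard refuses n > 60 by
default (raise `max_n` deliberately to accept the cost). The test and
acceptance suites use the sizes at which each authority is exact and fast:
nested-mode agreement on n ∈ [4, 30], grammar agreement on n ≤ 10 (both B6
settings), engine equivalence on n ≤ 20 with 1/2/6 workers, audits at
n ≤ 12, bounds at n ≤ 12, and the profiler trend on n ∈ {8, 12, 16, 20}.

Scores are IEEE doubles; with default unit weights all values are small
integers and every comparison is exact. `-Inf` is the forbidden score; it
never reaches a reported result because any structure scores ≥ 0 (the empty
structure is always derivable). Ties are broken by the fixed
first-alternative order above, making output bit-identical across engines
and platforms.

## Known limitations

* No energy model: stacking, loop penalties, dangles and temperature are out
  of scope, so predicted structures maximize pair count, not realism.
* One optimal structure is reported; suboptimal ensembles and partition
  functions are not computed.
* The grammar oracle's cache makes it an independent *implementation*, not
  an independent *formalism*; its agreement guards against coding errors in
  the fill order, vectorized slices and block decomposition, while the
  Nussinov and matching-bound oracles guard the recursion semantics.
* Layered dot-bracket output supports four bracket alphabets; structures
  needing five mutually crossing layers (not reachable at these problem
  sizes) raise a capacity error rather than silently dropping pairs.
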
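# knotfold

RNA secondary-structure prediction **with pseudoknots** by the one-hole
gap-matrix dynamic program, under base-pair maximization scoring — plus the
machinery that makes that O(n⁶) recursion observable: three work-block
execution strategies with a threshold scheduler, a per-matrix work profiler,
and independent verification oracles.

## Who this is for

Structural bioinformaticians and algorithm engineers who need a *transparent,
testable* reference implementation of the gap-matrix recursion system — the
scheme behind general pseudoknot prediction — rather than a black-box energy
minimizer. Everything is small, pure R, and cross-checked against independent
oracles.

## The model

A structure is a set of disjoint base pairs `(i, j)` with `i < j`. A pair may
form when `{base_i, base_j} ∈ {AU, GC, GU}` (configurable) and `j − i > h`
(minimum loop, default `h = 3`); each pair contributes its class weight
(default 1) and the optimum maximizes the total weight δ-sum.

Nested structures need only the two triangular matrices

```
vx(i,j) = δ(i,j) + wx(i+1, j−1)                  (i,j) itself pairs
wx(i,j) = max( vx(i,j), wx(i+1,j), wx(i,j−1),
               max_r wx(i,r) + wx(r+1,j),
               pk(i,j) )                          best with no assertion
```

Crossing pairs require the **one-hole gap matrix** `whx(i,j:k,l)`: the best
score of the two-segment region `[i,k] ∪ [l,j]` whose hole `[k+1, l−1]` is
left for an interleaving partner. The pseudoknot term composes two such
pieces whose holes are each other's material:

```
pk(i,j) = max_{a,b,c} whx(i,c:a,b) + whx(a+1,j:b−1,c+1)
```

`whx` itself is filled from six mutually independent **work blocks**: the
loop-free B1 (four trims plus the closures `zhx`/`yhx`/`vhx`, which pair the
outer ends, the hole flanks, or both) and five loops B2–B6 splitting a
segment against a `wx` region or, in the gap-gap block B6, into two gapped
pieces. With B6 on, the fill is Θ(n⁶) time and Θ(n⁴) space — which is why
the WHX fill dominates every profile and is the natural target for the three
execution strategies:

* **C-Par** — each block of a cell goes whole to one worker,
* **D-Par** — all loop iterations are flattened and chunked evenly,
* **H-Par** — a scheduler engages workers only when a cell carries at least
  5 iterations for each of at least 2 workers (6 workers, 30 iterations, is
  full utilization).

All engines produce bit-identical tables; the traceback is deterministic.

## A worked example

```r
library(knotfold)

fold <- predict_structure("GGGGAAAACCCCUUUU", id = "H-type")
fold
#> <knot_fold> H-type  n = 16  score = 8  engine = serial
#>    GGGGAAAACCCCUUUU
#>    (((([[[[))))]]]]
```

The 16-mer G⁴A⁴C⁴U⁴ folds into two interleaved helices — four G·C pairs and
four A·U pairs crossing them — reaching the analytic maximum of n/2 = 8
pairs. Layered dot-bracket shows the crossing: `()` is one helix, `[]` the
other. Nested-only prediction caps at 4:

```r
predict_structure("GGGGAAAACCCCUUUU",
                  options = dp_options(pseudoknots = FALSE))$score
#> [1] 4

glance(fold)
#> # A tibble: 1 × 7
#>   id         n score n_pairs n_layers pseudoknotted engine
#>   <chr>  <int> <dbl>   <int>    <int> <lgl>         <chr>
#> 1 H-type    16     8       8        2 TRUE          serial
```

Where the work goes (deterministic operation counts; WHX dominates and its
share grows with n):

```r
profile_run(fixture_sequences("random", n = 12, seed = 3)$residues)
#> <knot_profile> n = 12  pseudoknots = TRUE  elapsed = 0.512s
#> # A tibble: 6 × 5
#>   family cells   ops seconds   share
#>   <chr>  <int> <dbl>   <dbl>   <dbl>
#> 1 VX        66    66 0.00700 0.00358
#> 2 WX        66  1771 0.0210  0.0961
#> 3 WHX      715 14443 0.377   0.784
#> 4 VHX      715   715 0.0210  0.0388
#> 5 ZHX      715   715 0.0180  0.0388
#> 6 YHX      715   715 0.0300  0.0388
```

From a shell (the same functions behind a thin script):

```sh
inst/scripts/knotfold fixtures --kind pseudoknot --m 4 --out pk.fasta
inst/scripts/knotfold predict --engine hpar pk.fasta
inst/scripts/knotfold verify --n-max 10 --trials 25 --seed 7
```

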
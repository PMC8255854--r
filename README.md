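# msashort

Exact sum-of-pairs multiple sequence alignment for *very short* sequences.

Most multiple sequence alignment (MSA) work targets a handful of long
sequences; `msashort` looks at the opposite corner: many sequences of length
one, two or three, where exact answers are computable and sharp statements
can be made. The package is for people studying the combinatorics of
alignment scoring — when is the *trivial* (gapless) alignment already
optimal, and which score schemes break that optimality?

## The model

An alignment of sequences `s1, …, sk` over an alphabet Σ is a k×ℓ matrix
whose row *i*, with gaps removed, equals `si`. A **score scheme** is a
distance `d` on Σ ∪ {−}; it is a *metric* when `d(u,v) = 0 ⇔ u = v`,
`d(u,v) = d(v,u)`, and `d(u,w) ≤ d(u,v) + d(v,w)` for all symbols. The
**unit metric** prices every mismatch (gap included) at 1. The
**sum-of-pairs (SP) cost** of an alignment is

```
SP(A) = Σ_{i<j} cost(s'_i, s'_j),   cost(s'_i, s'_j) = Σ_m d(s'_i[m], s'_j[m])
```

equivalently a sum of within-column pair distances. The package provides:

* **Scoring** — `sp_cost()`, `pairwise_cost()`, `trivial_alignment()`,
  `normalize_alignment()`, with per-column and per-pair decompositions.
* **Score schemes** — `unit_metric()`, `score_scheme()`,
  `validate_scheme()` (axiom report with witnesses), `gap_dominance()`,
  `random_metric()` (metric-closure repaired), TSV read/write.
* **Closed forms** — for k pairwise-different length-1 sequences the
  optimum is `choose(k, 2)` under the unit metric
  (`optimal_cost_len1_unit()`), and `Σ_{i<j} d(a_i, a_j)` under any metric
  (`optimal_cost_len1()`); any ℓ-column alignment costs at most
  `k² − k/2 − k²/(2ℓ)` (`max_cost_len1_unit()`). For length-2 sets under
  the unit metric the trivial alignment is again optimal
  (`optimal_cost_len2_unit()`).
* **Exact solver** — `solve_exact()`, dynamic programming over the
  k-dimensional position lattice (the multi-sequence Needleman–Wunsch
  generalization), plus a full-enumeration oracle `solve_bruteforce()` /
  `enumerate_alignments()`.
* **Verification & search** — `verify_theorem()` replays the optimality
  results on randomized instances; `hunt_counterexamples()` looks for
  (sequence set, metric) pairs where the solver strictly beats the trivial
  alignment — for length-2 sequences that can only happen for metrics that
  are not *gap dominant* (`d(a,b) ≤ d(a,−)`).

## Worked example

The set `{CG, GC, GG}` over Σ = {C, G} with the metric `d(C,G) = 2`,
`d(C,−) = d(G,−) = 1`:

```r
library(msashort)

m <- read_scheme(system.file("extdata", "metric_cg.tsv", package = "msashort"))
seqs <- seq_set(c("CG", "GC", "GG"))

sp_cost(trivial_alignment(seqs), m)
#> <sp_cost> total 8 over 3 sequence(s), 2 column(s)
#>   per column: 4 + 4

solve_exact(seqs, m)
#> <msa_solve> optimal SP cost 6
#> <alignment> 3 x 3
#>   seq1  CG-
#>   seq2  -GC
#>   seq3  GG-
```

The gapless alignment costs 8, but gaps buy a strictly cheaper alignment of
cost 6 — possible only because this metric is not gap dominant
(`d(C,G) = 2 > d(C,−) = 1`). Under the unit metric the same set would be
trivially optimal. The analogous length-3 example:

```r
u <- unit_metric(c("C", "G"))
triplet <- seq_set(c("CCG", "GCG", "CGC"))
sp_cost(trivial_alignment(triplet), u)$total   # 6
solve_exact(triplet, u)$cost                   # 5
```

so even the unit metric loses trivial-optimality at length 3.

A command-line wrapper ships at
`system.file("cli", "msashort", package = "msashort")` with subcommands
`score`, `trivial`, `solve`, `validate-metric`, `closed-form`, `verify`
and `hunt`.

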
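---
title: "Exact sum-of-pairs alignment of very short sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact sum-of-pairs alignment of very short sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msashort)
```

## The problem

Multiple sequence alignment is NP-hard in general, but the hardness lives
in an unexpected corner of parameter space: for a *constant number* of
sequences the k-dimensional dynamic program is polynomial, while nothing
classical is known about *many very short* sequences. `msashort` works in
that short-sequence regime, where exact optima are computable and where
clean structural results exist: for length-1 sequences the gapless
("trivial") alignment is optimal under **any** metric score scheme, for
length-2 sequences it is optimal under the unit metric (and more generally
under any *gap-dominant* metric), and both statements fail one step
further — length-2 with a general metric, or length-3 with the unit metric.

This vignette records the model, the numerical and design choices, what the
randomized checks do and do not establish, and the package's limitations.

## Model and assumptions

An alignment of $s_1,\dots,s_k$ over alphabet $\Sigma$ is a $k \times \ell$
matrix over $\Sigma \cup \{-\}$ whose $i$-th row, after deleting gaps,
equals $s_i$. The gap symbol is reserved: it may not occur in input
sequences, and an alphabet may not contain it. A score scheme $d$ is a
symmetric non-negative table on $\Sigma \cup \{-\}$ with zero diagonal;
the sum-of-pairs cost is

$$\mathrm{SP}(A) \;=\; \sum_{i<j} \sum_{m=1}^{\ell} d\!\left(s'_i[m],\, s'_j[m]\right),$$

which decomposes equivalently by row pairs or by columns; `sp_cost()`
computes and cross-checks both decompositions.

Two structural facts shape the implementation:

* $d(-,-) = 0$ is forced by the zero diagonal. Hence all-gap columns are
  free, the canonical form of an alignment (`normalize_alignment()`) drops
  them, and — crucially — the SP cost is *column decomposable*, which is
  exactly what makes the lattice dynamic program correct. The solver
  asserts this property at solve time rather than assuming it.
* Identical sequences are aligned identically in some optimal alignment and
  cost 0 against each other, so all closed forms are evaluated over
  multisets directly: duplicates contribute zero terms and the multiset sum
  equals the distinct-sequence sum, while record identity is preserved for
  reporting. The solver likewise does not collapse duplicates (k stays
  small anyway).

Non-metric schemes are admitted for plain scoring — the SP cost is
well-defined for any symmetric non-negative table — but rejected (or warned
about) where a statement genuinely needs metric axioms: the closed forms
and, by default softly, the solver. `score_scheme()` therefore *diagnoses*
metricity and gap dominance as flags instead of enforcing them.

## Score schemes: parameters and validation

`validate_scheme()` checks identity of indiscernibles, symmetry, the
triangle inequality over all $|\Sigma \cup \{-\}|^3$ triples, and gap
dominance ($d(a,b) \le d(a,-)$ for all $a, b \in \Sigma$), reporting every
witness. Comparisons are exact for integral tables and use an absolute
tolerance of $10^{-9}$ otherwise; all shipped instances are integral, so
the worked costs match exactly.

`random_metric()` draws symmetric off-diagonal values — by default integers
in 1..4, a realistic substitution-cost scale that keeps arithmetic exact —
and repairs the table by its metric closure (all-pairs shortest paths on
the complete weighted graph over the symbols, via igraph). The closure
always terminates, is the identity on already-metric tables, and preserves
$d(u,v)=0 \Leftrightarrow u=v$ because all drawn weights are strictly
positive. The gap symbol is sampled like any other point of the space.

`random_gap_dominant_metric()` instead samples a metric on $\Sigma$ alone
and sets every gap distance to the constant $D = \max_{a,b} d(a,b)$. With a
constant gap distance the triangle inequality survives on every triple
through the gap, and $d(a,b) \le D = d(a,-)$ holds by construction, so the
family is exactly what the gap-dominance optimality check needs. It does
not cover gap-dominant metrics with *unequal* gap distances; the check is
therefore a sound but not exhaustive exploration of that class.

## The exact solver

`solve_exact()` runs dynamic programming over the lattice of per-sequence
positions: a state is a vector $(p_1,\dots,p_k)$ of characters consumed, a
transition advances a non-empty subset of sequences and emits one column,
and the value function is the minimal cost-to-go, computed backwards over
$\prod_i (|s_i|+1)$ states and $2^k - 1$ transitions each. Because all-gap
columns are free, restricting to these monotone paths loses no optimum —
every alignment normalizes to a path with unchanged cost.

Deliberate choices:

* **Tie-breaking.** Among co-optimal alignments the solver reports the one
  whose advance-subset sequence is lexicographically smallest ("advance"
  sorts before "gap", sequences in input order), reconstructed by a greedy
  forward walk over the value function. Output is therefore deterministic
  and diffable; `solve_bruteforce()` applies the same order, so the two
  engines return identical alignments, not just equal costs.
* **Limits.** Defaults `k_max = 6`, `l_max = 6` keep the state space at
  desk scale (at most $7^6$ states × 63 transitions); both are plain
  arguments, not hidden configuration. The solver is an oracle for
  theorem-checking, not a production aligner — no Carrillo–Lipman bounds,
  no heuristics.
* **Counting.** `count_optima = TRUE` runs a second pass accumulating the
  number of co-optimal canonical alignments; it is off by default since
  most callers only need one optimum.
* **Numerics.** Integral schemes are compared exactly; floating schemes
  with absolute tolerance $10^{-9}$ in the tie-breaking walk and oracle
  comparisons.

`enumerate_alignments()` generates every canonical alignment exactly once
(monotone lattice paths, lexicographic order) and refuses instances whose
path count — computed first by a cheap counting pass — exceeds its `limit`.
The counts grow violently: 13 paths for two length-2 sequences (the
Delannoy number), 16,081 for three length-3 sequences, and over $10^7$ for
four length-3 sequences, which is why the brute-force oracle is bounded.

## Randomized verification

`verify_theorem()` draws instances matching each result's hypotheses and
compares the solver optimum with the closed-form/trivial reference:

| id | instances | reference |
|----|-----------|-----------|
| `T4` | k ∈ 2..6 pairwise-different length-1, unit metric | `choose(k, 2)` |
| `T5` | k ∈ 2..5 length-1 (duplicates allowed), random metric | pairwise distance sum |
| `T6` | k ∈ 2..4 length-2, unit metric | columnwise mismatch count |
| `gap_dominance` | k ∈ 2..4, lengths 1–2, random gap-dominant metric | trivial cost |

The results are proved, so the tolerance is zero: a single mismatch is an
implementation bug and fails the suite. Every report carries its seed and,
on violation, the full instance (sequences plus metric TSV) as a
self-contained regression fixture. Length-1 runs use a six-letter alphabet
so that k = 6 distinct characters are samplable; length-2 runs use the
four-letter DNA alphabet — a deliberate nod to the data these sizes occur
in (k-mers, anchors, barcodes).

What passing does and does not show: the generator samples uniform
sequences and metric-closure-repaired integer metrics. It does not emulate
biased residue composition, similarity-derived (log-odds) substitution
matrices, affine gap penalties, or weighted SP variants — all outside this
model. Agreement on these instances validates the implementation of the
model, not the model's fit to any particular biological data.

`hunt_counterexamples()` inverts the question: it samples (metric, set)
pairs and returns those whose optimum is *strictly* below the trivial cost.
For length-2 sets every returned metric is certified non-gap-dominant (the
contrapositive of the optimality result; an internal assertion enforces
it). Which weaker property exactly characterizes trivially-optimal metrics
remains open — the hunter records per-instance witnesses and makes no
universal claim. The two canonical counterexamples — `{CG, GC, GG}` with
$d(C,G)=2$, gap distances 1 (trivial 8, optimal 6) and `{CCG, GCG, CGC}`
under the unit metric (trivial 6, optimal 5) — ship as fixtures and can be
replayed through the `instances` argument.

## Degenerate inputs and edge policies

* `trivial_alignment()` errors on unequal lengths — silent padding would
  corrupt every trivial-vs-optimal comparison.
* Empty sequences and all-gap rows are rejected at construction; all-gap
  *columns* are legal input (cost 0) but non-canonical.
* Typographic dashes (en/em dash, minus) are normalized to the ASCII gap on
  every input path; sequences are uppercased on read.
* `max_cost_len1_unit()` returns the exact fraction alongside the float
  when $k^2/(2\ell)$ is non-integral, avoiding float-equality surprises.

## Problem sizes used in the checks

The shipped test suite runs the verification matrix at 200 trials per
result and the DP-versus-enumeration oracle comparison at 500 sampled
instances with k ≤ 4 and lengths ≤ 3, capped at the enumeration bound of
50,000 canonical alignments per instance (which excludes only the
k = 4 × length-3 corner, at ten million paths). These sizes exercise every
code path of both engines; scaling the trial counts up is a matter of the
`trials` arguments.

## Limitations

* Linear gap costs only: no affine or position-dependent penalties, no
  similarity (maximization) scoring, no sequence weights.
* The solver is exponential in k by design; it answers questions about
  short-sequence structure, it does not align proteins.
* The counterexample hunter searches; it cannot certify that a metric
  keeps the trivial alignment optimal for *all* sequence sets.
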
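test_that("pairwise cost sums the per-column scheme distances", {
  expect_equal(pairwise_cost("CCG", "GCG", unit_cg()), 1)
  expect_equal(pairwise_cost("GCG", "GCG", unit_cg()), 0)
  expect_equal(pairwise_cost("GCG", "GCG", cg_metric()), 0)
  expect_equal(pairwise_cost("CG", "GC", cg_metric()), 4) # 2 + 2
  # symmetry in the two rows
  expect_equal(
    pairwise_cost("C-G", "GC-", cg_metric()),
    pairwise_cost("GC-", "C-G", cg_metric()))
})

test_that("pairwise cost rejects bad input", {
  expect_error(pairwise_cost("CG", "C", unit_cg()), "equal length")
  expect_error(pairwise_cost("CT", "CG", unit_cg()), "not covered")
})

test_that("sum-of-pairs cost reproduces the worked examples", {
  r1 <- sp_cost(triplet_aln(), unit_cg())
  expect_equal(r1$total, 5)
  expect_equal(r1$per_column, c(3, 0, 0, 2))

  r2 <- sp_cost(pair_aln(), cg_metric())
  expect_equal(r2$total, 6)
  expect_equal(r2$per_column, c(2, 2, 2))

  # identical rows, no gaps: every pair matches everywhere
  expect_equal(sp_cost(as_alignment(c("GCG", "GCG", "GCG")), unit_cg())$total, 0)
})

test_that("column and pair decompositions agree with the total", {
  for (seed in 1:25) {
    aln <- random_alignment(seed)
    scheme <- random_metric(c("A", "C", "G", "T"), seed = seed + 1000)
    r <- sp_cost(aln, scheme)
    expect_cost_equal(r$total, sum(r$per_column))
    expect_cost_equal(r$total, sum(r$per_pair$cost))
  }
})

test_that("sp_cost is invariant under row permutation and scales linearly", {
  for (seed in 1:15) {
    aln <- random_alignment(seed)
    scheme <- random_metric(c("A", "C", "G", "T"), seed = seed + 2000)
    total <- sp_cost(aln, scheme)$total
    perm <- withr::with_seed(seed, sample(nrow(aln)))
    shuffled <- as_alignment(aln[perm, ])
    expect_cost_equal(sp_cost(shuffled, scheme)$total, total)
    expect_cost_equal(sp_cost(aln, scale_scheme(scheme, 3))$total, 3 * total)
  }
})

test_that("trivial alignment is gapless and matches the stated costs", {
  t1 <- trivial_alignment(triplet_seqs())
  expect_equal(attr(t1, "n_col"), 3)
  expect_false(any(grepl("-", t1$aligned, fixed = TRUE)))
  expect_equal(sp_cost(t1, unit_cg())$total, 6)

  t2 <- trivial_alignment(pair_seqs())
  expect_equal(attr(t2, "n_col"), 2)
  expect_equal(sp_cost(t2, cg_metric())$total, 8)

  single <- trivial_alignment(seq_set("CCG"))
  expect_equal(single$aligned, "CCG")
  expect_equal(sp_cost(single, unit_cg())$total, 0)
})

test_that("trivial alignment refuses unequal lengths instead of padding", {
  expect_error(trivial_alignment(c("CG", "GCG")), "equal-length")
})

test_that("normalization drops exactly the all-gap columns", {
  aln <- as_alignment(c("C--", "G--"))
  norm <- normalize_alignment(aln)
  expect_equal(norm$aligned, c("C", "G"))
  # idempotent on canonical alignments
  expect_identical(normalize_alignment(norm)$aligned, norm$aligned)
  expect_identical(normalize_alignment(triplet_aln())$aligned, triplet_aln()$aligned)
  # de-gapped rows unchanged, cost unchanged, under random schemes
  for (seed in 1:15) {
    a <- as_alignment(c("C--G-", "-G-C-", "G---C"))
    scheme <- random_metric(c("C", "G"), seed = seed)
    expect_identical(alignment_source(normalize_alignment(a))$seq,
      alignment_source(a)$seq)
    expect_cost_equal(sp_cost(normalize_alignment(a), scheme)$total,
      sp_cost(a, scheme)$total)
  }
})

test_that("alignment construction enforces the de-gap invariant", {
  expect_error(as_alignment(c("CG-", "GC")), "same length")
  expect_error(as_alignment(c("C-G", "---")), "solely of gaps")
  expect_error(as_alignment(c("CG-", "GC-"), source = seq_set(c("CG", "CG"))),
    "must equal the source")
  # typographic dashes are normalized to the ASCII gap
  a <- as_alignment(c("C–G", "G−C"))
  expect_equal(a$aligned, c("C-G", "G-C"))
})

test_that("cost report tidiers expose the decompositions", {
  r <- sp_cost(triplet_aln(), unit_cg())
  td <- tidy(r)
  expect_equal(td$cost, c(3, 0, 0, 2))
  expect_equal(glance(r)$total, 5)
  expect_s3_class(autoplot(r), "ggplot")
})
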
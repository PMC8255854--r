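test_that("the lattice DP reproduces the printed optima", {
  s1 <- solve_exact(pair_seqs(), cg_metric())
  expect_equal(s1$cost, 6)
  s2 <- solve_exact(triplet_seqs(), unit_cg())
  expect_equal(s2$cost, 5)
  s3 <- solve_exact(c("C", "G", "T"), unit_metric(c("C", "G", "T")))
  expect_equal(s3$cost, 3)
})

test_that("solve results are internally consistent", {
  for (inst in list(
    list(seqs = pair_seqs(), scheme = cg_metric()),
    list(seqs = triplet_seqs(), scheme = unit_cg()))) {
    sol <- solve_exact(inst$seqs, inst$scheme)
    # reported cost is the SP cost of the reported alignment
    expect_cost_equal(sp_cost(sol$alignment, inst$scheme)$total, sol$cost)
    # canonical: no all-gap columns
    expect_identical(normalize_alignment(sol$alignment)$aligned,
      sol$alignment$aligned)
    # never worse than the trivial alignment
    expect_lte(sol$cost, sp_cost(trivial_alignment(inst$seqs), inst$scheme)$total)
  }
  g <- glance(solve_exact(pair_seqs(), cg_metric(), count_optima = TRUE))
  expect_true(g$optima_count >= 1)
})

test_that("degenerate instances are handled", {
  one <- solve_exact(seq_set("CCG"), unit_cg())
  expect_equal(one$cost, 0)
  expect_equal(one$alignment$aligned, "CCG")
  expect_equal(solve_bruteforce(seq_set("C"), unit_cg())$cost, 0)
  expect_error(solve_exact(rep_len(c("A", "B"), 7), unit_metric(c("A", "B"))),
    "k_max")
  expect_error(solve_exact("AAAAAAA", unit_metric("A")), "l_max")
})

test_that("non-metric schemes warn by default and error in strict mode", {
  broken <- matrix(c(0, 5, 1, 5, 0, 1, 1, 1, 0), 3, 3,
    dimnames = list(c("A", "B", "-"), c("A", "B", "-")))
  expect_warning(solve_exact(c("A", "B"), broken), "not a metric")
  expect_error(solve_exact(c("A", "B"), broken, strict = TRUE), "not a metric")
})

test_that("enumeration yields each canonical alignment exactly once", {
  # two length-1 sequences: aligned, and the two staggered orders
  three <- enumerate_alignments(c("A", "B"))
  expect_length(three, 3)
  keys <- vapply(three, function(a) paste(a$aligned, collapse = "|"), character(1))
  expect_setequal(keys, c("A-|-B", "A|B", "-A|B-"))
  expect_length(unique(keys), 3)

  # a single sequence aligns only to itself
  self <- enumerate_alignments(seq_set("CCG"))
  expect_length(self, 1)
  expect_equal(self[[1]]$aligned, "CCG")

  # the count for two sequences equals the Delannoy lattice-path number,
  # computed here by the independent two-step recurrence
  delannoy <- function(m, n) {
    D <- matrix(0, m + 1, n + 1)
    D[1, ] <- 1
    D[, 1] <- 1
    for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
      D[i, j] <- D[i - 1, j] + D[i, j - 1] + D[i - 1, j - 1]
    }
    D[m + 1, n + 1]
  }
  expect_length(enumerate_alignments(c("CG", "GC")), delannoy(2, 2))
  expect_length(enumerate_alignments(c("ACG", "GT")), delannoy(3, 2))
  expect_error(enumerate_alignments(c("ACGT", "ACGT", "ACGT", "ACGT", "ACGT")),
    "enumeration limit")
})

test_that("DP equals brute force on random 3-sequence instances", {
  ab <- c("A", "C", "G")
  for (seed in 1:60) {
    len <- 1 + seed %% 2
    seqs <- random_instance(3, len, ab, seed = seed)
    scheme <- if (seed %% 2 == 0) unit_metric(ab) else random_metric(ab, seed = seed + 300)
    dp <- solve_exact(seqs, scheme)
    bf <- solve_bruteforce(seqs, scheme)
    expect_cost_equal(dp$cost, bf$cost)
    # identical tie-break, identical reported alignment
    expect_identical(dp$alignment$aligned, bf$alignment$aligned)
  }
})

test_that("for two sequences under the unit metric the optimum is the edit distance", {
  ab <- c("A", "C", "G", "T")
  u <- unit_metric(ab)
  for (seed in 1:25) {
    seqs <- random_instance(2, 1 + seed %% 3, ab, seed = seed)
    expect_equal(
      solve_exact(seqs, u)$cost,
      as.numeric(utils::adist(seqs$seq[1], seqs$seq[2])))
  }
})

test_that("the optimum is invariant under sequence order and symbol relabeling", {
  ab <- c("A", "C", "G")
  for (seed in 1:15) {
    seqs <- random_instance(3, 2, ab, seed = seed)
    scheme <- random_metric(ab, seed = seed + 700)
    base <- solve_exact(seqs, scheme)$cost
    perm <- withr::with_seed(seed, sample(3))
    expect_cost_equal(solve_exact(seq_set(seqs$seq[perm]), scheme)$cost, base)
    # relabel A<->G consistently in sequences and scheme
    relabeled <- chartr("AG", "GA", seqs$seq)
    m <- msashort:::unclass_scheme(scheme)
    swap <- chartr("AG", "GA", rownames(m))
    dimnames(m) <- list(swap, swap)
    expect_cost_equal(
      solve_exact(seq_set(relabeled), score_scheme(m))$cost, base)
  }
})

test_that("the costliest alignment of k distinct characters is fully staggered", {
  for (k in 2:5) {
    chars <- LETTERS[1:k]
    u <- unit_metric(chars)
    costs <- vapply(enumerate_alignments(seq_set(chars)),
      function(a) sp_cost(a, u)$total, numeric(1))
    expect_equal(max(costs), k^2 - k)
    expect_equal(min(costs), optimal_cost_len1_unit(k))
  }
})
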
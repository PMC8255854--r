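test_that("the unit metric prices every mismatch at one, gap included", {
  u <- unit_cg()
  expect_equal(u["C", "G"], 1)
  expect_equal(u["C", "-"], 1)
  expect_equal(u["-", "-"], 0)
  expect_true(all(diag(unclass(u)) == 0))
  expect_true(attr(u, "is_metric"))
  expect_true(attr(u, "is_gap_dominant"))
})

test_that("the unit metric passes validation at every alphabet size", {
  for (n in 1:20) {
    v <- validate_scheme(unit_metric(LETTERS[seq_len(n)]))
    expect_true(attr(v, "is_metric"))
    expect_true(attr(v, "is_gap_dominant"))
    expect_true(all(v$pass))
  }
})

test_that("validation flags the two-letter metric as metric but not gap dominant", {
  v <- validate_scheme(cg_metric())
  expect_true(attr(v, "is_metric"))
  expect_false(attr(v, "is_gap_dominant"))
  w <- v$witness[[which(v$axiom == "gap_dominance")]]
  expect_true(nrow(w) > 0)
  expect_true(all(sort(unique(c(w$a, w$b))) == c("C", "G")))
})

test_that("triangle violations are reported with a witness triple", {
  m <- matrix(c(0, 5, 1, 5, 0, 1, 1, 1, 0), 3, 3,
    dimnames = list(c("A", "B", "-"), c("A", "B", "-")))
  v <- validate_scheme(m)
  expect_false(attr(v, "is_metric"))
  tri <- v$witness[[which(v$axiom == "triangle")]]
  # d(A, B) = 5 > d(A, -) + d(-, B) = 2, witnessed through the gap
  expect_true(any(tri$u != tri$w & tri$v == "-"))
})

test_that("gap dominance returns witnesses exactly when violated", {
  expect_true(gap_dominance(unit_cg())$is_gap_dominant)
  g <- gap_dominance(cg_metric())
  expect_false(g$is_gap_dominant)
  expect_true(any(g$witnesses$a == "C" & g$witnesses$b == "G"))
  # single-letter alphabet: vacuous off-diagonal, d(a,a)=0 <= d(a,-)
  expect_true(gap_dominance(unit_metric("A"))$is_gap_dominant)
})

test_that("scheme construction enforces symmetry, zero diagonal, gap coverage", {
  base <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
    dimnames = list(c("A", "B", "-"), c("A", "B", "-")))
  bad_sym <- base; bad_sym[1, 2] <- 2
  expect_error(score_scheme(bad_sym), "symmetric")
  bad_diag <- base; diag(bad_diag) <- c(1, 0, 0)
  expect_error(score_scheme(bad_diag), "diagonal")
  no_gap <- base[1:2, 1:2]
  expect_error(score_scheme(no_gap), "gap character")
  bad_neg <- base; bad_neg[1, 2] <- bad_neg[2, 1] <- -1
  expect_error(score_scheme(bad_neg), "non-negative")
})

test_that("random metrics are deterministic and always pass all axioms", {
  expect_identical(
    unclass(random_metric(c("A", "C", "G"), seed = 11)),
    unclass(random_metric(c("A", "C", "G"), seed = 11)))
  for (seed in 1:250) {
    s <- random_metric(c("A", "B", "C"), seed = seed)
    v <- validate_scheme(s)
    expect_true(attr(v, "is_metric"))
  }
  for (seed in 1:50) {
    s <- random_gap_dominant_metric(c("A", "B", "C"), seed = seed)
    expect_true(attr(s, "is_metric"))
    expect_true(gap_dominance(s)$is_gap_dominant)
  }
})

test_that("shortest-path repair is the identity on tables already metric", {
  u <- unclass(unit_metric(c("A", "B")))
  attributes(u) <- attributes(u)[c("dim", "dimnames")]
  expect_equal(msashort:::metric_closure(u), u)
  m <- cg_metric()
  m0 <- msashort:::unclass_scheme(m)
  expect_equal(msashort:::metric_closure(m0), m0)
})

test_that("score schemes round-trip through the TSV dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scheme(cg_metric(), f)
  back <- read_scheme(f)
  expect_equal(unclass(back)[rownames(cg_metric()), colnames(cg_metric())],
    unclass(cg_metric())[, ])
  expect_true(attr(back, "is_metric"))
  # the shipped fixture parses to the same scheme
  shipped <- read_scheme(system.file("extdata", "metric_cg.tsv", package = "msashort"))
  expect_equal(shipped["C", "G"], 2)
  expect_equal(shipped["G", "-"], 1)
})
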
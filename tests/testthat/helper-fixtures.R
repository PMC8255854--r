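# Worked instances used throughout: the 3x3 {CCG, GCG, CGC} set with its
# printed gapped alignment, and the {CG, GC, GG} set with the two-letter
# metric d(C,G) = 2, d(C,-) = d(G,-) = 1.

triplet_seqs <- function() seq_set(c(s1 = "CCG", s2 = "GCG", s3 = "CGC"))
triplet_aln <- function() as_alignment(c(s1 = "CCG-", s2 = "GCG-", s3 = "-CGC"))

pair_seqs <- function() seq_set(c(s1 = "CG", s2 = "GC", s3 = "GG"))
pair_aln <- function() as_alignment(c(s1 = "-CG", s2 = "GC-", s3 = "G-G"))

cg_metric <- function() {
  score_scheme(matrix(
    c(0, 2, 1,
      2, 0, 1,
      1, 1, 0), 3, 3, byrow = TRUE,
    dimnames = list(c("C", "G", "-"), c("C", "G", "-"))))
}

unit_cg <- function() unit_metric(c("C", "G"))
unit_dna <- function() unit_metric(c("A", "C", "G", "T"))

# scale every distance of a scheme by c > 0 (stays a valid scheme)
scale_scheme <- function(scheme, by) {
  m <- matrix(as.numeric(scheme), nrow(scheme), ncol(scheme),
    dimnames = dimnames(scheme))
  score_scheme(m * by)
}

# random gapped alignment: random sequences, then random gap insertion to a
# common length -- for invariance properties, not optimality
random_alignment <- function(seed, k = 3, alphabet = c("A", "C", "G", "T")) {
  withr::with_seed(seed, {
    lens <- sample(1:3, k, replace = TRUE)
    width <- max(lens) + sample(0:2, 1)
    rows <- vapply(lens, function(len) {
      chars <- sample(alphabet, len, replace = TRUE)
      pos <- sort(sample(width, len))
      row <- rep("-", width)
      row[pos] <- chars
      paste(row, collapse = "")
    }, character(1))
    # guard against an all-gap column making the alignment non-scorable? it
    # is scorable; guard only against an empty (impossible: len >= 1) row
    as_alignment(rows, alphabet = alphabet)
  })
}

expect_cost_equal <- function(a, b) {
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-9)
}
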
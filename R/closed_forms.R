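#' Optimal SP cost of k distinct length-1 sequences under the unit metric
#'
#' For k pairwise-different single characters the trivial alignment is
#' optimal and costs `choose(k, 2)`: every pair of rows mismatches exactly
#' once.
#'
#' @param k Number of pairwise-different length-1 sequences (k >= 1).
#' @return The integer `k * (k - 1) / 2`.
#' @examples
#' optimal_cost_len1_unit(4)
#' @export
optimal_cost_len1_unit <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != round(k)) {
    abort("`k` must be a positive integer.")
  }
  choose(k, 2)
}

#' Maximum SP cost of aligning k distinct characters on l columns
#'
#' Any alignment of k pairwise-different length-1 sequences on `l` columns
#' costs `k^2 - (k + sum(k_i^2)) / 2` where `k_i` counts the characters in
#' column i; minimizing `sum(k_i^2)` over occupancy profiles gives the
#' upper bound `k^2 - k/2 - k^2/(2l)`. At `l = k` (one character per
#' column) the bound is attained and equals `k^2 - k`; at `l = 1` it
#' collapses to the optimum `choose(k, 2)`.
#'
#' @param k Number of distinct length-1 sequences.
#' @param l Number of alignment columns, `1 <= l <= k`.
#' @return The bound as a numeric; when `k^2 / (2 * l)` is non-integral the
#'   exact value is also attached as a `fraction` attribute
#'   `c(numerator, denominator)`.
#' @examples
#' max_cost_len1_unit(4, 4) # 12 = k^2 - k
#' @export
max_cost_len1_unit <- function(k, l) {
  if (length(k) != 1 || k < 1 || k != round(k)) abort("`k` must be a positive integer.")
  if (length(l) != 1 || l < 1 || l > k || l != round(l)) {
    abort("`l` must be an integer with 1 <= l <= k.")
  }
  num <- 2 * l * k^2 - l * k - k^2   # value = num / (2 l), exact integer arithmetic
  den <- 2 * l
  out <- num / den
  if (num %% den != 0) {
    g <- gcd2(num, den)
    attr(out, "fraction") <- c(numerator = num / g, denominator = den / g)
  }
  out
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' SP cost of an alignment of length-1 sequences with a given occupancy
#'
#' For k distinct characters placed so that column i holds `counts[i]` of
#' them (one character per row), the unit-metric SP cost is
#' `k^2 - (k + sum(counts^2)) / 2`.
#'
#' @param counts Positive integer occupancy profile `(k_1, ..., k_l)`.
#' @return The cost as a numeric.
#' @export
occupancy_cost <- function(counts) {
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("Occupancy counts must be positive integers.")
  }
  k <- sum(counts)
  k^2 - (k + sum(counts^2)) / 2
}

#' All occupancy profiles of k characters over l columns
#'
#' Enumerates the compositions of k into l positive parts — every way of
#' distributing k length-1 sequences over l non-empty alignment columns.
#'
#' @inheritParams max_cost_len1_unit
#' @return A list of integer vectors, each summing to `k`, length `l`.
#' @export
occupancy_profiles <- function(k, l) {
  if (l < 1 || l > k) abort("Need 1 <= l <= k.")
  if (l == 1) return(list(k))
  out <- list()
  for (first in seq_len(k - l + 1)) {
    for (rest in occupancy_profiles(k - first, l - 1)) {
      out[[length(out) + 1]] <- c(first, rest)
    }
  }
  out
}

#' Optimal SP cost of length-1 sequences under an arbitrary metric
#'
#' For single-character sequences under any metric the trivial alignment is
#' optimal, with cost the sum of pairwise distances over all record pairs.
#' Duplicate characters contribute zero to each other, so the multiset sum
#' equals the distinct-sequence sum.
#'
#' @param seqs A [seq_set()] of length-1 sequences.
#' @param scheme A metric [score_scheme()] covering the alphabet.
#' @return The optimal cost, `sum_{i<j} d(s_i, s_j)`.
#' @examples
#' optimal_cost_len1(c("A", "B", "C"), unit_metric(c("A", "B", "C")))
#' @export
optimal_cost_len1 <- function(seqs, scheme) {
  seqs <- seq_set(seqs)
  scheme <- score_scheme(scheme)
  if (any(nchar(seqs$seq) != 1)) {
    abort("All sequences must have length 1.")
  }
  if (!is_metric(scheme)) {
    abort("The closed form requires a metric score scheme.")
  }
  m <- unclass_scheme(scheme)
  missing <- setdiff(unique(seqs$seq), rownames(m))
  if (length(missing)) {
    abort(paste0("Symbol(s) not covered by the score scheme: ",
      paste(missing, collapse = ", ")))
  }
  k <- nrow(seqs)
  if (k == 1) return(0)
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  sum(m[cbind(seqs$seq[pairs[, 1]], seqs$seq[pairs[, 2]])])
}

#' Optimal SP cost of length-2 sequences under the unit metric
#'
#' For two-character sequences under the unit metric the trivial alignment
#' is optimal: the cost is the number of mismatching first-character pairs
#' plus the number of mismatching second-character pairs.
#'
#' @param seqs A [seq_set()] of length-2 sequences.
#' @return The optimal integer cost; equals
#'   `sp_cost(trivial_alignment(seqs), unit_metric(...))$total`.
#' @examples
#' optimal_cost_len2_unit(c("CG", "GC", "GG"))
#' @export
optimal_cost_len2_unit <- function(seqs) {
  seqs <- seq_set(seqs)
  if (any(nchar(seqs$seq) != 2)) {
    abort("All sequences must have length 2.")
  }
  k <- nrow(seqs)
  if (k == 1) return(0)
  first <- substr(seqs$seq, 1, 1)
  second <- substr(seqs$seq, 2, 2)
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  sum(first[pairs[, 1]] != first[pairs[, 2]]) +
    sum(second[pairs[, 1]] != second[pairs[, 2]])
}
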
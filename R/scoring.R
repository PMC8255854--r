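#' Cost of an aligned pair of rows
#'
#' The cost of aligning two equal-length rows is the sum, over columns, of
#' the scheme distance between the paired characters:
#' `sum_i d(row1[i], row2[i])`.
#'
#' @param row1,row2 Aligned rows (equal-length strings over the alphabet
#'   plus the gap character).
#' @param scheme A [score_scheme()].
#' @return A non-negative number, symmetric in the two rows.
#' @examples
#' pairwise_cost("CCG", "GCG", unit_metric(c("C", "G")))
#' @export
pairwise_cost <- function(row1, row2, scheme) {
  scheme <- score_scheme(scheme)
  row1 <- toupper(normalize_gaps(row1))
  row2 <- toupper(normalize_gaps(row2))
  if (nchar(row1) != nchar(row2)) {
    abort("Aligned rows must have equal length.")
  }
  c1 <- split_chars(row1)[[1]]
  c2 <- split_chars(row2)[[1]]
  m <- unclass_scheme(scheme)
  missing <- setdiff(unique(c(c1, c2)), rownames(m))
  if (length(missing)) {
    abort(paste0("Symbol(s) not covered by the score scheme: ",
      paste(missing, collapse = ", ")))
  }
  sum(m[cbind(c1, c2)])
}

#' Sum-of-pairs cost of a multiple alignment
#'
#' The sum-of-pairs (SP) cost of a k-row alignment is the sum of the
#' pairwise alignment costs over all k(k-1)/2 row pairs; equivalently the
#' sum over columns of all within-column pair distances. Both
#' decompositions are computed and returned.
#'
#' @param aln An [as_alignment()] (or aligned rows accepted by it).
#' @param scheme A [score_scheme()].
#' @return An object of class `"sp_cost"`: a list with `total`,
#'   `per_column` (numeric, one entry per column), `per_pair` (tibble with
#'   `id1`, `id2`, `cost`), `n_seq`, `n_col`.
#' @examples
#' a <- as_alignment(c("CCG-", "GCG-", "-CGC"))
#' sp_cost(a, unit_metric(c("C", "G")))
#' @export
sp_cost <- function(aln, scheme) {
  aln <- as_alignment(aln)
  scheme <- score_scheme(scheme)
  m <- unclass_scheme(scheme)
  cm <- alignment_matrix(aln)
  missing <- setdiff(unique(as.vector(cm)), rownames(m))
  if (length(missing)) {
    abort(paste0("Symbol(s) not covered by the score scheme: ",
      paste(missing, collapse = ", ")))
  }
  k <- nrow(cm)
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  per_column <- vapply(seq_len(ncol(cm)), function(j) {
    col <- cm[, j]
    sum(m[cbind(col[pairs[, 1]], col[pairs[, 2]])])
  }, numeric(1))
  per_pair <- tibble(
    id1 = aln$id[pairs[, 1]],
    id2 = aln$id[pairs[, 2]],
    cost = vapply(seq_len(nrow(pairs)), function(r) {
      sum(m[cbind(cm[pairs[r, 1], ], cm[pairs[r, 2], ])])
    }, numeric(1)))
  total <- sum(per_column)
  stopifnot(isTRUE(all.equal(total, sum(per_pair$cost), tolerance = 1e-9)))
  structure(
    list(total = total, per_column = per_column, per_pair = per_pair,
      n_seq = k, n_col = ncol(cm)),
    class = "sp_cost")
}

#' @export
print.sp_cost <- function(x, ...) {
  cat("<sp_cost> total ", format(x$total), " over ", x$n_seq, " sequence(s), ",
    x$n_col, " column(s)\n", sep = "")
  cat("  per column:", paste(format(x$per_column), collapse = " + "), "\n")
  invisible(x)
}

#' @describeIn sp_cost Per-column costs as a tibble (`column`, `cost`).
#' @param x An `"sp_cost"` object.
#' @param ... Unused.
#' @export
tidy.sp_cost <- function(x, ...) {
  tibble(column = seq_len(x$n_col), cost = x$per_column)
}

#' @describeIn sp_cost One-row summary (`total`, `n_seq`, `n_col`).
#' @export
glance.sp_cost <- function(x, ...) {
  tibble(total = x$total, n_seq = x$n_seq, n_col = x$n_col)
}

#' @describeIn sp_cost Bar chart of the per-column cost decomposition.
#' @param object An `"sp_cost"` object.
#' @export
autoplot.sp_cost <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$column, y = .data$cost)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "alignment column", y = "sum-of-pairs cost",
      title = sprintf("SP cost %s across %d columns",
        format(object$total), object$n_col)) +
    ggplot2::theme_minimal()
}
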
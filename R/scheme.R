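#' Construct a score scheme
#'
#' A score scheme is a symmetric non-negative cost table `d` over the
#' alphabet plus the gap character, used to price each aligned character
#' pair. A scheme is a *metric* when it additionally satisfies identity of
#' indiscernibles (`d(u, v) = 0` iff `u == v`) and the triangle inequality
#' `d(u, w) <= d(u, v) + d(v, w)` for every triple, the gap symbol included.
#' It is *gap dominant* when `d(a, b) <= d(a, -)` for all alphabet
#' characters `a`, `b` — the one property of the unit metric that keeps the
#' gapless alignment optimal for length-2 sequences.
#'
#' Construction enforces symmetry, a zero diagonal (so `d(-, -) = 0` always
#' holds) and non-negativity; the metric and gap-dominance properties are
#' diagnosed and stored as flags, not enforced, so that non-metric cost
#' tables can still be scored.
#'
#' @param m A square numeric matrix with identical row and column names
#'   covering the alphabet and the gap character `"-"` (typographic dashes
#'   are normalized).
#' @return The matrix with class `"score_scheme"` and attributes
#'   `is_metric`, `is_gap_dominant`, `alphabet`.
#' @examples
#' m <- matrix(c(0, 2, 1, 2, 0, 1, 1, 1, 0), 3, 3,
#'   dimnames = list(c("C", "G", "-"), c("C", "G", "-")))
#' score_scheme(m)
#' @export
score_scheme <- function(m) {
  if (inherits(m, "score_scheme")) return(m)
  if (!is.matrix(m) || !is.numeric(m)) abort("`m` must be a numeric matrix.")
  if (nrow(m) != ncol(m)) abort("Score scheme matrix must be square.")
  rn <- toupper(normalize_gaps(rownames(m) %||% character()))
  cn <- toupper(normalize_gaps(colnames(m) %||% character()))
  if (length(rn) != nrow(m) || !identical(rn, cn)) {
    abort("Score scheme matrix needs identical row and column names.")
  }
  if (anyDuplicated(rn)) abort("Score scheme symbols must be unique.")
  if (!gap_char() %in% rn) {
    abort("Score scheme must cover the gap character \"-\".")
  }
  dimnames(m) <- list(rn, cn)
  tol <- scheme_tol(m)
  if (any(is.na(m))) abort("Score scheme table is incomplete (NA entries).")
  if (any(m < -tol)) abort("Score scheme distances must be non-negative.")
  if (any(abs(m - t(m)) > tol)) abort("Score scheme must be symmetric.")
  if (any(abs(diag(m)) > tol)) abort("Score scheme diagonal must be zero (d(u, u) = 0).")
  diag(m) <- 0
  m[] <- (m + t(m)) / 2
  v <- scheme_axioms(m, tol)
  structure(m,
    alphabet = alphabet(setdiff(rn, gap_char())),
    is_metric = all(v$pass[v$axiom %in% c("identity", "symmetry", "triangle")]),
    is_gap_dominant = all(v$pass[v$axiom == "gap_dominance"]),
    class = "score_scheme")
}

# exact comparison for integral tables, 1e-9 otherwise
scheme_tol <- function(m) {
  if (all(m == round(m), na.rm = TRUE)) 0 else 1e-9
}

# one row per axiom check with witness coordinates
scheme_axioms <- function(m, tol = scheme_tol(m)) {
  syms <- rownames(m)
  n <- length(syms)
  ab <- setdiff(syms, gap_char())
  out <- list()
  off <- which(upper.tri(m) & m <= tol, arr.ind = TRUE)
  out$identity <- tibble(
    axiom = "identity", pass = nrow(off) == 0,
    witness = if (nrow(off)) list(tibble(u = syms[off[, 1]], v = syms[off[, 2]]))
      else list(tibble(u = character(), v = character())))
  asym <- which(abs(m - t(m)) > tol & upper.tri(m), arr.ind = TRUE)
  out$symmetry <- tibble(
    axiom = "symmetry", pass = nrow(asym) == 0,
    witness = if (nrow(asym)) list(tibble(u = syms[asym[, 1]], v = syms[asym[, 2]]))
      else list(tibble(u = character(), v = character())))
  tri <- expand.grid(u = seq_len(n), v = seq_len(n), w = seq_len(n))
  bad <- tri[m[cbind(tri$u, tri$w)] > m[cbind(tri$u, tri$v)] + m[cbind(tri$v, tri$w)] + tol, ]
  out$triangle <- tibble(
    axiom = "triangle", pass = nrow(bad) == 0,
    witness = list(tibble(u = syms[bad$u], v = syms[bad$v], w = syms[bad$w])))
  gd <- expand.grid(a = ab, b = ab, stringsAsFactors = FALSE)
  gdbad <- gd[m[cbind(gd$a, gd$b)] > m[cbind(gd$a, rep(gap_char(), nrow(gd)))] + tol, ]
  out$gap_dominance <- tibble(
    axiom = "gap_dominance", pass = nrow(gdbad) == 0,
    witness = list(tibble(a = gdbad$a, b = gdbad$b)))
  dplyr::bind_rows(out)
}

#' The unit metric over an alphabet
#'
#' The most common score scheme: every mismatched pair of symbols — the gap
#' included — costs 1, every match costs 0. It is a metric and is gap
#' dominant.
#'
#' @param alphabet An [alphabet()] or character vector of symbols.
#' @return A [score_scheme()].
#' @examples
#' unit_metric(c("C", "G"))
#' @export
unit_metric <- function(alphabet) {
  ab <- as_alphabet(alphabet)
  syms <- c(unclass(ab), gap_char())
  m <- matrix(1, length(syms), length(syms), dimnames = list(syms, syms))
  diag(m) <- 0
  score_scheme(m)
}

#' Validate a score scheme against the metric axioms
#'
#' Checks identity of indiscernibles, symmetry, the triangle inequality
#' (over all triples of symbols, gap included) and gap dominance, reporting
#' every violated axiom together with the witness pair or triple.
#'
#' @param scheme A [score_scheme()] or a square numeric matrix.
#' @return An object of class `"scheme_validation"`: a tibble with columns
#'   `axiom`, `pass`, `witness` (list column of witness tibbles), carrying
#'   `is_metric` and `is_gap_dominant` attributes.
#' @examples
#' validate_scheme(unit_metric(c("A", "C", "G", "T")))
#' @export
validate_scheme <- function(scheme) {
  scheme <- score_scheme(scheme)
  v <- scheme_axioms(unclass_scheme(scheme))
  structure(v,
    is_metric = attr(scheme, "is_metric"),
    is_gap_dominant = attr(scheme, "is_gap_dominant"),
    class = c("scheme_validation", class(v)))
}

#' @export
print.scheme_validation <- function(x, ...) {
  cat("<scheme_validation> is_metric:", attr(x, "is_metric"),
    " is_gap_dominant:", attr(x, "is_gap_dominant"), "\n")
  for (i in seq_len(nrow(x))) {
    w <- x$witness[[i]]
    cat(sprintf("  %-13s %s", x$axiom[i], if (x$pass[i]) "PASS" else "FAIL"))
    if (!x$pass[i] && nrow(w)) {
      cat("  e.g. (", paste(unlist(w[1, ]), collapse = ", "), ")", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Test gap dominance of a score scheme
#'
#' Gap dominance — `d(a, b) <= d(a, -)` for all alphabet characters — is the
#' only property of the unit metric used in the proof that the trivial
#' alignment is optimal for length-2 sequences, so any metric with it
#' inherits that optimality.
#'
#' @inheritParams validate_scheme
#' @return A list with `is_gap_dominant` (logical) and `witnesses` (tibble
#'   of violating pairs `a`, `b`, with their distances).
#' @examples
#' gap_dominance(unit_metric(c("C", "G")))
#' @export
gap_dominance <- function(scheme) {
  scheme <- score_scheme(scheme)
  m <- unclass_scheme(scheme)
  ab <- unclass(attr(scheme, "alphabet"))
  tol <- scheme_tol(m)
  gd <- expand.grid(a = ab, b = ab, stringsAsFactors = FALSE)
  gd$d_ab <- m[cbind(gd$a, gd$b)]
  gd$d_a_gap <- m[cbind(gd$a, rep(gap_char(), nrow(gd)))]
  bad <- as_tibble(gd[gd$d_ab > gd$d_a_gap + tol, ])
  list(is_gap_dominant = nrow(bad) == 0, witnesses = bad)
}

#' Sample a random metric over an alphabet
#'
#' Draws symmetric positive off-diagonal distances uniformly over
#' `value_range`, then repairs the table into a true metric by taking its
#' metric closure (all-pairs shortest paths on the complete weighted graph,
#' gap symbol included as an ordinary point of the space). The closure is
#' the identity on tables that already satisfy the triangle inequality.
#'
#' @param alphabet An [alphabet()] or character vector.
#' @param seed Integer seed; the same seed always yields the same scheme.
#' @param value_range Length-2 numeric, the sampling range for off-diagonal
#'   draws (default integers 1..4, a realistic substitution-cost scale).
#' @param integer Draw integer values (default) or continuous uniform.
#' @return A [score_scheme()] with `is_metric = TRUE`.
#' @examples
#' random_metric(c("A", "C", "G"), seed = 1)
#' @export
random_metric <- function(alphabet, seed, value_range = c(1, 4), integer = TRUE) {
  ab <- as_alphabet(alphabet)
  if (length(value_range) != 2 || diff(range(value_range)) < 0 ||
    min(value_range) <= 0) {
    abort("`value_range` must be two positive values, low <= high.")
  }
  syms <- c(unclass(ab), gap_char())
  n <- length(syms)
  m <- matrix(0, n, n, dimnames = list(syms, syms))
  npair <- n * (n - 1) / 2
  vals <- withr::with_seed(seed, {
    if (integer) {
      sample(seq(ceiling(value_range[1]), floor(value_range[2])), npair, replace = TRUE)
    } else {
      stats::runif(npair, value_range[1], value_range[2])
    }
  })
  vals <- pmax(vals, min(value_range))  # keep off-diagonals strictly positive
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  score_scheme(metric_closure(m))
}

# all-pairs shortest paths on the complete weighted graph over the symbols
metric_closure <- function(m) {
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected", weighted = TRUE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  d[rownames(m), colnames(m)]
}

#' Sample a random gap-dominant metric
#'
#' Samples a metric on the alphabet alone, then sets every gap distance to
#' the constant `D = max d(a, b)`. With constant gap distances the triangle
#' inequality is preserved on all triples involving the gap, and
#' `d(a, b) <= D = d(a, -)` holds by construction.
#'
#' @inheritParams random_metric
#' @return A [score_scheme()] with `is_metric` and `is_gap_dominant` TRUE.
#' @export
random_gap_dominant_metric <- function(alphabet, seed, value_range = c(1, 4),
                                       integer = TRUE) {
  ab <- as_alphabet(alphabet)
  syms <- unclass(ab)
  if (length(syms) == 1) {
    return(unit_metric(ab))
  }
  n <- length(syms)
  npair <- n * (n - 1) / 2
  vals <- withr::with_seed(seed, {
    if (integer) {
      sample(seq(ceiling(value_range[1]), floor(value_range[2])), npair, replace = TRUE)
    } else {
      stats::runif(npair, value_range[1], value_range[2])
    }
  })
  m <- matrix(0, n, n, dimnames = list(syms, syms))
  m[upper.tri(m)] <- pmax(vals, min(value_range))
  m <- metric_closure(m + t(m))
  D <- max(m)
  full <- rbind(cbind(m, rep(D, n)), c(rep(D, n), 0))
  dimnames(full) <- list(c(syms, gap_char()), c(syms, gap_char()))
  score_scheme(full)
}

#' @export
print.score_scheme <- function(x, ...) {
  cat("<score_scheme> over {",
    paste(unclass(attr(x, "alphabet")), collapse = ", "), "} + gap;",
    " metric:", attr(x, "is_metric"),
    " gap_dominant:", attr(x, "is_gap_dominant"), "\n")
  print(unclass_scheme(x))
  invisible(x)
}

unclass_scheme <- function(x) {
  y <- unclass(x)
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  y
}

is_metric <- function(scheme) isTRUE(attr(scheme, "is_metric"))

#' Read a score scheme from a TSV matrix
#'
#' The dialect is a square symmetric tab-separated matrix: the first row
#' holds the symbols (gap `"-"` included), each following row a symbol label
#' then its numeric distances.
#'
#' @param path Path to the TSV file.
#' @return A [score_scheme()].
#' @export
read_scheme <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  colnames(m) <- normalize_gaps(colnames(m))
  rownames(m) <- normalize_gaps(rownames(m))
  score_scheme(m)
}

#' Write a score scheme as a TSV matrix
#'
#' @param scheme A [score_scheme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  scheme <- score_scheme(scheme)
  m <- unclass_scheme(scheme)
  df <- data.frame(symbol = rownames(m), m, check.names = FALSE)
  names(df)[1] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
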
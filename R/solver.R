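# Shared machinery for the k-dimensional position lattice.
#
# A canonical alignment of k sequences corresponds one-to-one to a monotone
# path from the origin to (len_1, ..., len_k): each step advances a
# non-empty subset of sequences by one character and emits one column
# (advanced sequences contribute their next character, the rest a gap).
# Because d(-,-) = 0 for every valid scheme, dropping all-gap columns loses
# no optima, so the path model is exhaustive over canonical alignments.

# Non-empty advance subsets in tie-break order: "advance" sorts before
# "gap", sequence 1 most significant. Rows of the returned logical matrix.
advance_subsets <- function(k) {
  g <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))[-(2^k), , drop = FALSE]
  key <- apply(g, 1, function(r) paste(ifelse(r, "0", "1"), collapse = ""))
  m <- g[order(key), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

solver_setup <- function(seqs, scheme, strict = FALSE) {
  seqs <- seq_set(seqs)
  scheme <- score_scheme(scheme)
  m <- unclass_scheme(scheme)
  stopifnot(m[gap_char(), gap_char()] == 0)  # column-decomposability of SP cost
  if (!is_metric(scheme)) {
    msg <- "Score scheme is not a metric; the SP optimum is still well-defined."
    if (strict) abort(msg) else warn(msg)
  }
  syms <- rownames(m)
  chars <- split_chars(seqs$seq)
  bad <- setdiff(unique(unlist(chars)), syms)
  if (length(bad)) {
    abort(paste0("Symbol(s) not covered by the score scheme: ",
      paste(bad, collapse = ", ")))
  }
  k <- nrow(seqs)
  lens <- nchar(seqs$seq)
  dims <- lens + 1L
  strides <- cumprod(c(1, dims[-k]))
  list(
    seqs = seqs, scheme = scheme, m = m, k = k, lens = lens,
    dims = dims, strides = strides, nstates = prod(dims),
    gap_i = match(gap_char(), syms),
    seq_i = lapply(chars, match, table = syms),
    subsets = advance_subsets(k),
    pairs = which(upper.tri(diag(k)), arr.ind = TRUE),
    tol = if (scheme_tol(m) == 0) 0 else 1e-9)
}

decode_state <- function(idx0, s) ((idx0 %/% s$strides) %% s$dims)

# cost of the column emitted when subset `adv` advances out of position p
column_cost <- function(s, p, adv) {
  if (s$k == 1) return(0)
  ch <- rep.int(s$gap_i, s$k)
  for (i in which(adv)) ch[i] <- s$seq_i[[i]][p[i] + 1L]
  sum(s$m[cbind(ch[s$pairs[, 1]], ch[s$pairs[, 2]])])
}

column_chars <- function(s, p, adv) {
  ch <- rep.int(gap_char(), s$k)
  for (i in which(adv)) ch[i] <- rownames(s$m)[s$seq_i[[i]][p[i] + 1L]]
  ch
}

#' Exact minimum sum-of-pairs alignment of a small sequence set
#'
#' Global SP optimum by dynamic programming over the k-dimensional lattice
#' of per-sequence positions (the classical multi-sequence generalization
#' of Needleman-Wunsch). Each transition advances a non-empty subset of the
#' sequences and emits one alignment column; the value function is the
#' minimal cost-to-go, computed backwards, and the reported alignment is
#' the optimal path whose advance-subset sequence is lexicographically
#' smallest ("advance" before "gap", sequences in input order) — a
#' deterministic tie-break among co-optima.
#'
#' This is an oracle for very short sequences, not a production aligner:
#' the state space is `prod(len_i + 1)` and each state considers
#' `2^k - 1` transitions.
#'
#' @param seqs A [seq_set()] (or anything it accepts), `k >= 1` sequences.
#' @param scheme A [score_scheme()]; non-metric schemes are allowed with a
#'   warning (the optimum is still well-defined) unless `strict = TRUE`.
#' @param k_max,l_max Guard rails on the number and length of sequences
#'   (defaults 6 and 6); exceeding them is an error.
#' @param count_optima Also count the number of co-optimal canonical
#'   alignments (a second counting pass).
#' @param strict Error (rather than warn) on non-metric schemes.
#' @return An object of class `"msa_solve"`: list with `alignment` (the
#'   canonical optimal [as_alignment()]), `cost`, `optima_count` (or NA),
#'   and `explored` (diagnostic counters).
#' @examples
#' solve_exact(c("CCG", "GCG", "CGC"), unit_metric(c("C", "G")))
#' @export
solve_exact <- function(seqs, scheme, k_max = 6, l_max = 6,
                        count_optima = FALSE, strict = FALSE) {
  s <- solver_setup(seqs, scheme, strict = strict)
  if (s$k > k_max) {
    abort(sprintf("Instance has %d sequences; limit k_max = %d.", s$k, k_max))
  }
  if (max(s$lens) > l_max) {
    abort(sprintf("Longest sequence has %d characters; limit l_max = %d.",
      max(s$lens), l_max))
  }
  n <- s$nstates
  V <- rep(Inf, n)
  V[n] <- 0
  n_trans <- 0L
  if (n > 1) {
    for (idx in (n - 1):1) {
      p <- decode_state(idx - 1, s)
      best <- Inf
      for (r in seq_len(nrow(s$subsets))) {
        adv <- s$subsets[r, ]
        if (any(adv & p >= s$lens)) next
        n_trans <- n_trans + 1L
        v <- column_cost(s, p, adv) + V[idx + sum(s$strides[adv])]
        if (v < best) best <- v
      }
      V[idx] <- best
    }
  }
  # forward greedy walk: first optimal subset in tie-break order each step
  p <- rep(0L, s$k)
  cols <- character(0)
  rows <- matrix(character(0), nrow = s$k, ncol = 0)
  while (any(p < s$lens)) {
    idx <- 1 + sum(p * s$strides)
    for (r in seq_len(nrow(s$subsets))) {
      adv <- s$subsets[r, ]
      if (any(adv & p >= s$lens)) next
      nidx <- idx + sum(s$strides[adv])
      if (column_cost(s, p, adv) + V[nidx] <= V[idx] + s$tol) {
        rows <- cbind(rows, column_chars(s, p, adv))
        p <- p + adv
        break
      }
    }
  }
  optima <- NA_integer_
  if (count_optima) {
    N <- numeric(n)
    N[n] <- 1
    if (n > 1) {
      for (idx in (n - 1):1) {
        p2 <- decode_state(idx - 1, s)
        tot <- 0
        for (r in seq_len(nrow(s$subsets))) {
          adv <- s$subsets[r, ]
          if (any(adv & p2 >= s$lens)) next
          nidx <- idx + sum(s$strides[adv])
          if (column_cost(s, p2, adv) + V[nidx] <= V[idx] + s$tol) {
            tot <- tot + N[nidx]
          }
        }
        N[idx] <- tot
      }
    }
    optima <- N[1]
  }
  aln <- as_alignment(
    setNames(apply(rows, 1, paste, collapse = ""), s$seqs$id),
    source = s$seqs)
  structure(
    list(alignment = aln, cost = V[1], optima_count = optima,
      explored = list(n_states = n, n_transitions = n_trans),
      seqs = s$seqs, scheme = s$scheme),
    class = "msa_solve")
}

#' @export
print.msa_solve <- function(x, ...) {
  cat("<msa_solve> optimal SP cost ", format(x$cost), "\n", sep = "")
  print(x$alignment)
  if (!is.na(x$optima_count)) {
    cat("  co-optimal alignments:", x$optima_count, "\n")
  }
  invisible(x)
}

#' @describeIn solve_exact Per-pair cost decomposition of the optimum as a
#'   tibble.
#' @param x,object An `"msa_solve"` object.
#' @param ... Unused.
#' @export
tidy.msa_solve <- function(x, ...) {
  sp_cost(x$alignment, x$scheme)$per_pair
}

#' @describeIn solve_exact One-row summary: cost, dimensions, search size.
#' @export
glance.msa_solve <- function(x, ...) {
  tibble(cost = x$cost, n_seq = nrow(x$seqs),
    n_col = attr(x$alignment, "n_col"),
    optima_count = x$optima_count,
    n_states = x$explored$n_states,
    n_transitions = x$explored$n_transitions)
}

# number of canonical alignments (monotone lattice paths) of the instance
count_alignments <- function(seqs) {
  seqs <- seq_set(seqs)
  k <- nrow(seqs)
  lens <- nchar(seqs$seq)
  dims <- lens + 1L
  strides <- cumprod(c(1, dims[-k]))
  n <- prod(dims)
  subs <- advance_subsets(k)
  C <- numeric(n)
  C[n] <- 1
  if (n > 1) {
    for (idx in (n - 1):1) {
      p <- ((idx - 1) %/% strides) %% dims
      tot <- 0
      for (r in seq_len(nrow(subs))) {
        adv <- subs[r, ]
        if (any(adv & p >= lens)) next
        tot <- tot + C[idx + sum(strides[adv])]
      }
      C[idx] <- tot
    }
  }
  C[1]
}

#' Enumerate every canonical alignment of a tiny sequence set
#'
#' Generates each canonical alignment (no all-gap columns) exactly once as
#' a monotone column decomposition, in deterministic lexicographic order of
#' the advance-subset sequence. Intended as an independent brute-force
#' oracle; the number of alignments explodes quickly, so a hard limit on
#' the enumeration size is enforced.
#'
#' @inheritParams solve_exact
#' @param max_columns Maximum number of columns (default `sum(len_i)`, the
#'   length of the fully staggered alignment, which never binds).
#' @param limit Maximum number of alignments to enumerate (default 50000);
#'   the count is computed first by a lattice path-count and exceeding the
#'   limit is an error.
#' @return A list of [as_alignment()] objects.
#' @examples
#' length(enumerate_alignments(c("CG", "GC"))) # 13 monotone paths
#' @export
enumerate_alignments <- function(seqs, max_columns = NULL, limit = 50000) {
  seqs <- seq_set(seqs)
  k <- nrow(seqs)
  lens <- nchar(seqs$seq)
  max_columns <- max_columns %||% sum(lens)
  if (max_columns < max(lens)) {
    abort("`max_columns` must be at least the longest sequence length.")
  }
  n_aln <- count_alignments(seqs)
  if (n_aln > limit) {
    abort(sprintf(
      "Instance has %s canonical alignments; enumeration limit is %s.",
      format(n_aln, big.mark = ","), format(limit, big.mark = ",")))
  }
  chars <- split_chars(seqs$seq)
  subs <- advance_subsets(k)
  acc <- new.env(parent = emptyenv())
  acc$out <- vector("list", n_aln)
  acc$i <- 0L
  rec <- function(p, cols) {
    if (all(p == lens)) {
      acc$i <- acc$i + 1L
      rows <- apply(cols, 1, paste, collapse = "")
      acc$out[[acc$i]] <- as_alignment(setNames(rows, seqs$id), source = seqs)
      return(invisible())
    }
    if (ncol(cols) >= max_columns) return(invisible())
    for (r in seq_len(nrow(subs))) {
      adv <- subs[r, ]
      if (any(adv & p >= lens)) next
      col <- vapply(seq_len(k), function(i) {
        if (adv[i]) chars[[i]][p[i] + 1L] else gap_char()
      }, character(1))
      rec(p + adv, cbind(cols, col))
    }
    invisible()
  }
  rec(rep(0L, k), matrix(character(0), nrow = k, ncol = 0))
  acc$out[seq_len(acc$i)]
}

#' Brute-force minimum SP alignment by full enumeration
#'
#' Exhaustive depth-first search over every canonical alignment,
#' accumulating column costs along the way — no memoization, so it is an
#' independent check on [solve_exact()]. Same tie-break: the first optimum
#' in lexicographic advance-subset order is reported.
#'
#' @inheritParams enumerate_alignments
#' @return An `"msa_solve"` object (with `optima_count` from the search).
#' @examples
#' solve_bruteforce(c("CG", "GC", "GG"), unit_metric(c("C", "G")))
#' @export
solve_bruteforce <- function(seqs, scheme, max_columns = NULL, limit = 50000,
                             strict = FALSE) {
  s <- solver_setup(seqs, scheme, strict = strict)
  max_columns <- max_columns %||% sum(s$lens)
  n_aln <- count_alignments(s$seqs)
  if (n_aln > limit) {
    abort(sprintf(
      "Instance has %s canonical alignments; enumeration limit is %s.",
      format(n_aln, big.mark = ","), format(limit, big.mark = ",")))
  }
  acc <- new.env(parent = emptyenv())
  acc$best <- Inf
  acc$rows <- NULL
  acc$n_opt <- 0
  acc$n_seen <- 0
  rec <- function(p, cost, cols) {
    if (all(p == s$lens)) {
      acc$n_seen <- acc$n_seen + 1
      if (cost < acc$best - s$tol) {
        acc$best <- cost
        acc$rows <- cols
        acc$n_opt <- 1
      } else if (cost <= acc$best + s$tol) {
        acc$n_opt <- acc$n_opt + 1
      }
      return(invisible())
    }
    if (ncol(cols) >= max_columns) return(invisible())
    for (r in seq_len(nrow(s$subsets))) {
      adv <- s$subsets[r, ]
      if (any(adv & p >= s$lens)) next
      cc <- column_cost(s, p, adv)
      rec(p + adv, cost + cc, cbind(cols, column_chars(s, p, adv)))
    }
    invisible()
  }
  rec(rep(0L, s$k), 0, matrix(character(0), nrow = s$k, ncol = 0))
  aln <- as_alignment(
    setNames(apply(acc$rows, 1, paste, collapse = ""), s$seqs$id),
    source = s$seqs)
  structure(
    list(alignment = aln, cost = acc$best, optima_count = acc$n_opt,
      explored = list(n_states = s$nstates, n_transitions = acc$n_seen),
      seqs = s$seqs, scheme = s$scheme),
    class = "msa_solve")
}
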
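#' Sample a random sequence set
#'
#' Uniform sampling of k sequences of a fixed length over an alphabet,
#' optionally without replacement on sequence content. Deterministic for a
#' given seed.
#'
#' @param k Number of sequences.
#' @param seq_len Common sequence length.
#' @param alphabet An [alphabet()] or character vector.
#' @param seed Integer seed.
#' @param distinct Require pairwise-different sequence content (needs
#'   `|alphabet|^seq_len >= k`).
#' @return A [seq_set()].
#' @examples
#' random_instance(3, 2, c("C", "G"), seed = 1)
#' @export
random_instance <- function(k, seq_len, alphabet, seed, distinct = FALSE) {
  ab <- unclass(as_alphabet(alphabet))
  if (k < 1 || seq_len < 1) abort("`k` and `seq_len` must be positive.")
  n_space <- length(ab)^seq_len
  if (distinct && n_space < k) {
    abort(sprintf(
      "Cannot draw %d distinct sequences: only %d exist over this alphabet.",
      k, n_space))
  }
  seqs <- withr::with_seed(seed, {
    if (distinct) {
      # enumerate the (small) sequence space and sample without replacement
      space <- apply(
        expand.grid(rep(list(ab), seq_len), stringsAsFactors = FALSE),
        1, paste, collapse = "")
      sample(space, k)
    } else {
      vapply(seq_len(k), function(i) {
        paste(sample(ab, seq_len, replace = TRUE), collapse = "")
      }, character(1))
    }
  })
  seq_set(seqs, alphabet = ab)
}

theorem_ids <- c("T4", "T5", "T6", "gap_dominance")

#' Randomized verification of the trivial-alignment optimality results
#'
#' Generates random instances matching one result's hypotheses, solves each
#' exactly, and compares the solver optimum against the closed-form /
#' trivial-alignment cost. The results are proved, so any violation within
#' solver limits is an implementation bug.
#'
#' * `"T4"` — pairwise-different length-1 sequences, unit metric: optimum
#'   must equal `choose(k, 2)` (and the trivial cost).
#' * `"T5"` — length-1 sequences (duplicates allowed), random metric:
#'   optimum must equal the pairwise-distance sum [optimal_cost_len1()].
#' * `"T6"` — length-2 sequences, unit metric: optimum must equal
#'   [optimal_cost_len2_unit()] (the trivial cost).
#' * `"gap_dominance"` — lengths 1 or 2, random gap-dominant metric:
#'   optimum must equal the trivial cost.
#'
#' @param theorem One of `"T4"`, `"T5"`, `"T6"`, `"gap_dominance"`.
#' @param trials Number of random instances (default 200).
#' @param seed Integer seed; reports are replayable.
#' @param k_range Integer range the number of sequences is drawn from.
#'   Defaults follow the verification matrix: 2..6 for T4, 2..5 for T5,
#'   2..4 for T6 and gap_dominance.
#' @param alphabet Alphabet to sample from (default `A..F` for length-1
#'   runs, `A,C,G,T` otherwise).
#' @return An object of class `"msa_verification"`: list with `theorem`,
#'   `trials`, `seed`, `results` (one tibble row per trial) and
#'   `violations` (tibble, with full instances as list columns; empty on a
#'   correct implementation).
#' @examples
#' verify_theorem("T4", trials = 20, seed = 1)
#' @export
verify_theorem <- function(theorem, trials = 200, seed = 1,
                           k_range = NULL, alphabet = NULL) {
  theorem <- match.arg(theorem, theorem_ids)
  k_range <- k_range %||% switch(theorem,
    T4 = 2:6, T5 = 2:5, T6 = 2:4, gap_dominance = 2:4)
  alphabet <- as_alphabet(alphabet %||% switch(theorem,
    T4 = LETTERS[1:6], T5 = LETTERS[1:4],
    T6 = c("A", "C", "G", "T"), gap_dominance = c("A", "C", "G", "T")))
  draws <- withr::with_seed(seed, {
    tibble(
      trial = seq_len(trials),
      k = k_range[sample.int(length(k_range), trials, replace = TRUE)],
      sub_seed = sample.int(.Machine$integer.max - 1, trials))
  })
  unit <- unit_metric(alphabet)
  rows <- purrr::pmap(draws, function(trial, k, sub_seed) {
    len <- switch(theorem,
      T4 = 1L, T5 = 1L, T6 = 2L,
      gap_dominance = if (sub_seed %% 2 == 0) 1L else 2L)
    inst_seqs <- random_instance(k, len, alphabet, seed = sub_seed,
      distinct = theorem == "T4")
    scheme <- switch(theorem,
      T4 = unit,
      T5 = random_metric(alphabet, seed = sub_seed + 1),
      T6 = unit,
      gap_dominance = random_gap_dominant_metric(alphabet, seed = sub_seed + 1))
    reference <- switch(theorem,
      T4 = optimal_cost_len1_unit(k),
      T5 = optimal_cost_len1(inst_seqs, scheme),
      T6 = optimal_cost_len2_unit(inst_seqs),
      gap_dominance = sp_cost(trivial_alignment(inst_seqs), scheme)$total)
    trivial <- sp_cost(trivial_alignment(inst_seqs), scheme)$total
    sol <- solve_exact(inst_seqs, scheme)
    tibble(
      trial = trial, k = k, seq_len = len, sub_seed = sub_seed,
      seqs = paste(inst_seqs$seq, collapse = ","),
      optimum = sol$cost, reference = reference, trivial_cost = trivial,
      violated = abs(sol$cost - reference) > 1e-9,
      instance = list(list(seqs = inst_seqs, scheme = scheme, solution = sol)))
  })
  results <- dplyr::bind_rows(rows)
  structure(
    list(theorem = theorem, trials = trials, seed = seed,
      results = dplyr::select(results, -"instance"),
      violations = dplyr::filter(results, .data$violated)),
    class = "msa_verification")
}

#' @export
print.msa_verification <- function(x, ...) {
  cat("<msa_verification> ", x$theorem, ": ", x$trials, " trials, seed ",
    x$seed, ", ", nrow(x$violations), " violation(s)\n", sep = "")
  if (nrow(x$violations)) {
    print(dplyr::select(x$violations, -"instance"))
  }
  invisible(x)
}

#' @describeIn verify_theorem Per-trial results tibble.
#' @param x,object An `"msa_verification"` object.
#' @param ... Unused.
#' @export
tidy.msa_verification <- function(x, ...) x$results

#' @describeIn verify_theorem One-row summary.
#' @export
glance.msa_verification <- function(x, ...) {
  tibble(theorem = x$theorem, trials = x$trials, seed = x$seed,
    violations = nrow(x$violations),
    max_abs_gap = if (nrow(x$results)) max(abs(x$results$optimum - x$results$reference)) else 0)
}

#' @describeIn verify_theorem Solver optimum vs. closed-form reference per
#'   trial.
#' @export
autoplot.msa_verification <- function(object, ...) {
  ggplot2::ggplot(object$results,
    ggplot2::aes(x = .data$reference, y = .data$optimum)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "closed-form / trivial cost", y = "solver optimum",
      title = sprintf("%s: %d trials, %d violation(s)",
        object$theorem, object$trials, nrow(object$violations))) +
    ggplot2::theme_minimal()
}

#' Hunt for instances where the trivial alignment is beaten
#'
#' Samples random metrics and equal-length sequence sets, solves each
#' instance exactly, and returns every (sequence set, scheme) pair whose
#' optimal SP cost is strictly below the trivial-alignment cost. For
#' length-2 sequences, gap dominance makes the trivial alignment optimal,
#' so every returned scheme is certified non-gap-dominant; which weaker
#' property characterizes trivially-optimal metrics is open, hence the
#' search.
#'
#' @param seq_len Common sequence length (>= 2; length-1 sets can yield no
#'   counterexample under any metric).
#' @param alphabet_size Alphabet size for sampling (symbols `A`, `B`, ...).
#' @param n_schemes Number of random metrics to try.
#' @param n_sets Number of random sequence sets per metric.
#' @param k Sequences per set (default 3).
#' @param seed Integer seed.
#' @param instances Optional explicit list of `list(seqs =, scheme =)`
#'   instances to test instead of sampling (so known counterexamples can be
#'   replayed).
#' @return A tibble of class `"msa_counterexamples"`: one row per
#'   counterexample with `seqs` (comma-joined), `trivial_cost`,
#'   `optimal_cost`, `gap_dominant`, and list columns `seq_set`, `scheme`,
#'   `witness` (the beating alignment).
#' @examples
#' hunt_counterexamples(seq_len = 2, alphabet_size = 2, n_schemes = 5,
#'   n_sets = 5, seed = 1)
#' @export
hunt_counterexamples <- function(seq_len = 2, alphabet_size = 2,
                                 n_schemes = 20, n_sets = 20, k = 3,
                                 seed = 1, instances = NULL) {
  if (is.null(instances)) {
    if (seq_len < 2) {
      abort("`seq_len` must be >= 2: length-1 sets have no counterexamples under any metric.")
    }
    ab <- as_alphabet(LETTERS[seq_len(alphabet_size)])
    sub_seeds <- withr::with_seed(seed,
      sample.int(.Machine$integer.max - 1, n_schemes * (n_sets + 1)))
    instances <- list()
    i <- 0
    for (sch in seq_len(n_schemes)) {
      scheme <- random_metric(ab, seed = sub_seeds[i + 1])
      for (st in seq_len(n_sets)) {
        seqs <- random_instance(k, seq_len, ab, seed = sub_seeds[i + 1 + st])
        instances[[length(instances) + 1]] <- list(seqs = seqs, scheme = scheme)
      }
      i <- i + n_sets + 1
    }
  }
  rows <- purrr::map(instances, function(inst) {
    inst_seqs <- seq_set(inst$seqs)
    scheme <- score_scheme(inst$scheme)
    trivial <- sp_cost(trivial_alignment(inst_seqs), scheme)$total
    sol <- solve_exact(inst_seqs, scheme)
    if (sol$cost >= trivial - 1e-9) return(NULL)
    gd <- gap_dominance(scheme)$is_gap_dominant
    if (all(nchar(inst_seqs$seq) == 2) && gd) {
      abort("Internal error: a gap-dominant scheme beat the trivial alignment on length-2 sequences.")
    }
    tibble(
      seqs = paste(inst_seqs$seq, collapse = ","),
      trivial_cost = trivial, optimal_cost = sol$cost,
      gap_dominant = gd,
      seq_set = list(inst_seqs), scheme = list(scheme),
      witness = list(sol$alignment))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(seqs = character(), trivial_cost = numeric(),
      optimal_cost = numeric(), gap_dominant = logical(),
      seq_set = list(), scheme = list(), witness = list())
  }
  structure(out, seed = seed,
    class = c("msa_counterexamples", class(tibble())))
}

#' @export
print.msa_counterexamples <- function(x, ...) {
  cat("<msa_counterexamples> ", nrow(x),
    " instance(s) where the optimum beats the trivial alignment\n", sep = "")
  if (nrow(x)) {
    print(as_tibble(x)[c("seqs", "trivial_cost", "optimal_cost", "gap_dominant")])
  }
  invisible(x)
}

# serialize a verification or counterexample report for YAML/JSON output;
# alignments rendered as aligned FASTA blocks
report_to_list <- function(x) {
  if (inherits(x, "msa_verification")) {
    list(
      theorem = x$theorem, trials = x$trials, seed = x$seed,
      violations = nrow(x$violations),
      results = lapply(seq_len(nrow(x$results)), function(i) as.list(x$results[i, ])))
  } else if (inherits(x, "msa_counterexamples")) {
    list(
      seed = attr(x, "seed"),
      counterexamples = lapply(seq_len(nrow(x)), function(i) {
        list(
          sequences = x$seq_set[[i]]$seq,
          metric = scheme_to_tsv_string(x$scheme[[i]]),
          trivial_cost = x$trivial_cost[i],
          optimal_cost = x$optimal_cost[i],
          gap_dominant = x$gap_dominant[i],
          witness = alignment_to_fasta_string(x$witness[[i]]))
      }))
  } else {
    abort("Unsupported report type.")
  }
}

scheme_to_tsv_string <- function(scheme) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_scheme(scheme, f)
  paste(readLines(f), collapse = "\n")
}

alignment_to_fasta_string <- function(aln) {
  paste(paste0(">", aln$id, "\n", aln$aligned), collapse = "\n")
}
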
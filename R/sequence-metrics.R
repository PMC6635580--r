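# internal: coerce labels-or-counts input into a count vector
as_counts <- function(x) {
  if (is.character(x) || is.factor(x)) {
    as.numeric(table(x))
  } else if (is.numeric(x)) {
    if (any(x < 0)) stop_attnrl("counts must be nonnegative", "attnrl_invalid_input")
    as.numeric(x)
  } else {
    stop_attnrl("expected a label sequence or a vector of counts", "attnrl_invalid_input")
  }
}

#' Shannon entropy of a choice distribution
#'
#' `S = -sum p_i log(p_i)` (natural log) over the empirical choice
#' frequencies; zero-count categories contribute nothing. Entropy is 0 for a
#' fully biased chooser and `log(N)` for uniform choice over N options.
#'
#' @param counts Nonnegative counts (or rates) per option, sum > 0.
#' @return The entropy in nats.
#' @examples
#' choice_entropy(c(0.099, 0.266, 0.585, 0.049))
#' @export
choice_entropy <- function(counts) {
  counts <- as_counts(counts)
  tot <- sum(counts)
  if (tot <= 0) stop_attnrl("counts must have a positive sum", "attnrl_invalid_input")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Bias index of a choice sequence
#'
#' `B = 1 - S_emp / S_max` with `S_max = log(n_options)`: 0 for uniform,
#' fully exploratory choice and 1 for exclusive choice of a single option.
#' Base-invariant (the log base cancels in the ratio).
#'
#' @param x A label sequence (character/factor) or a vector of counts/rates.
#' @param n_options Alphabet size used for `S_max`; defaults to the number of
#'   count categories (or distinct labels).
#' @return The bias index in \[0, 1\].
#' @examples
#' b_index(c(0.099, 0.266, 0.585, 0.049))
#' @export
b_index <- function(x, n_options = NULL) {
  counts <- as_counts(x)
  n_options <- n_options %||% length(counts)
  if (n_options < 2) stop_attnrl("n_options must be >= 2", "attnrl_invalid_input")
  1 - choice_entropy(counts) / log(n_options)
}

#' Run lengths of a choice sequence
#'
#' A run is a maximal block of identical consecutive choices. Runs never
#' cross session boundaries: a session break terminates the current run
#' (sessions were separate days with re-randomized item locations).
#'
#' @param labels Label sequence.
#' @param sessions Optional per-trial session index (same length as
#'   `labels`).
#' @return Integer vector of run lengths; they always sum to
#'   `length(labels)`.
#' @examples
#' extract_runs(strsplit("AAABABBCACD", "")[[1]])
#' @export
extract_runs <- function(labels, sessions = NULL) {
  if (length(labels) == 0) stop_attnrl("empty sequence", "attnrl_invalid_input")
  if (is.null(sessions)) return(rle(as.character(labels))$lengths)
  stopifnot(length(sessions) == length(labels))
  unlist(lapply(split(as.character(labels), sessions), function(y) rle(y)$lengths),
         use.names = FALSE)
}

#' Sorted reference sequence
#'
#' The fully persistent reference: the same multiset of labels grouped into
#' one block per label, in canonical (sorted) label order; for example
#' AAABABBCACD becomes AAAAABBBCCD. Idempotent.
#'
#' @param labels Label sequence.
#' @return The sorted sequence.
#' @export
sorted_reference <- function(labels) {
  if (length(labels) == 0) stop_attnrl("empty sequence", "attnrl_invalid_input")
  sort(as.character(labels))
}

#' Complementary cumulative run-length distribution
#'
#' Tabulates run lengths and their complementary cumulative distribution
#' `P(X >= x)`. Run-length distributions of persistent choice sequences are
#' heavy-tailed to the right, which is why they are compared on log-log
#' scales; the CCDF keeps `log P` well-defined down the tail.
#'
#' @param x A label sequence, or an integer vector of run lengths.
#' @param sessions Optional session index (label input only).
#' @return A tibble of class `"run_distribution"` with columns `length`, `n`,
#'   `ccdf`, and attribute `run_lengths`.
#' @export
run_distribution <- function(x, sessions = NULL) {
  lengths <- if (is.character(x) || is.factor(x)) extract_runs(x, sessions) else {
    if (any(x < 1) || any(x != round(x))) {
      stop_attnrl("run lengths must be positive integers", "attnrl_invalid_input")
    }
    as.integer(x)
  }
  support <- sort(unique(lengths))
  n <- vapply(support, function(s) sum(lengths == s), numeric(1))
  ccdf <- rev(cumsum(rev(n))) / length(lengths)
  out <- tibble::tibble(length = support, n = n, ccdf = ccdf)
  structure(out, run_lengths = lengths,
            class = c("run_distribution", class(out)))
}

# internal: CCDF evaluated on the integer grid 1..xmax, floored
ccdf_grid <- function(lengths, xmax, floor = 1e-12) {
  counts <- tabulate(lengths, nbins = xmax)
  pmax(rev(cumsum(rev(counts))) / length(lengths), floor)
}

# internal: area between two floored CCDFs given on the grid 1..xmax,
# integrated over u = ln x by the trapezoidal rule
area_grid <- function(p1, p2) {
  u <- log(seq_along(p1))
  f <- abs(log(p1) - log(p2))
  if (length(u) < 2) return(0)
  pracma::trapz(u, f)
}

#' Area test statistic between two run distributions
#'
#' The area between two cumulative run-length distributions on log-log
#' scales, `A = integral |ln P1(u) - ln P2(u)| du` with `u = ln x`, evaluated
#' on the union integer grid of run lengths and integrated by the trapezoidal
#' rule. Both distributions are floored at 1e-12 wherever their CCDF is zero,
#' so the log transform stays finite. Symmetric and nonnegative; 0 for
#' identical distributions.
#'
#' @param p1,p2 [run_distribution()] objects, or integer run-length vectors.
#' @return The area statistic (a nonnegative number).
#' @export
area_statistic <- function(p1, p2) {
  l1 <- if (inherits(p1, "run_distribution")) attr(p1, "run_lengths") else as.integer(p1)
  l2 <- if (inherits(p2, "run_distribution")) attr(p2, "run_lengths") else as.integer(p2)
  xmax <- max(l1, l2)
  area_grid(ccdf_grid(l1, xmax), ccdf_grid(l2, xmax))
}

#' Persistence index of a choice sequence
#'
#' The ratio of two averaged area statistics: the numerator compares the
#' empirical sequence's run distribution with those of `n_shuffles` random
#' label permutations, the denominator compares the sorted reference (fully
#' persistent) sequence with the same permutations. An index of 0 indicates
#' past-independent choice, 1 fully perseverative choice. Values above 1 are
#' possible for pathological inputs and are not clamped.
#'
#' @param labels Label sequence (>= 2 distinct labels).
#' @param sessions Optional session index; runs never cross session breaks,
#'   and with `by_session = TRUE` the index is computed per session (labels
#'   shuffled within session) and the session mean returned.
#' @param n_shuffles Number of random permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param by_session Compute per session and average.
#' @return The persistence index (a single number). With
#'   `by_session = TRUE`, the session mean with the per-session values in
#'   attribute `"sessions"`.
#' @export
p_index <- function(labels, sessions = NULL, n_shuffles = 1000, seed = 1,
                    by_session = FALSE) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop_attnrl("persistence index is undefined for a single-label sequence",
                "attnrl_undefined_index")
  }
  set.seed(seed)
  if (by_session) {
    if (is.null(sessions)) stop_attnrl("by_session = TRUE needs `sessions`",
                                       "attnrl_invalid_input")
    vals <- vapply(split(labels, sessions), function(y) {
      if (length(unique(y)) < 2) NA_real_ else p_index_one(y, NULL, n_shuffles)
    }, numeric(1))
    return(structure(mean(vals, na.rm = TRUE), sessions = vals))
  }
  p_index_one(labels, sessions, n_shuffles)
}

# internal: the ratio-of-mean-areas computation; uses the current RNG state
p_index_one <- function(labels, sessions, n_shuffles) {
  n <- length(labels)
  emp <- extract_runs(labels, sessions)
  srt <- extract_runs(sorted_reference(labels), sessions)
  xmax_all <- n
  num <- den <- numeric(n_shuffles)
  for (j in seq_len(n_shuffles)) {
    shuf <- extract_runs(sample(labels), sessions)
    xmax <- max(emp, srt, shuf)
    pshuf <- ccdf_grid(shuf, xmax)
    num[j] <- area_grid(ccdf_grid(emp, xmax), pshuf)
    den[j] <- area_grid(ccdf_grid(srt, xmax), pshuf)
  }
  mean(num) / mean(den)
}

#' Bias and persistence indices together
#'
#' @inheritParams p_index
#' @param n_options Alphabet size for the bias index.
#' @return A one-row tibble with `b_index`, `p_index`, `n_shuffles`, `seed`.
#' @export
bp_indices <- function(labels, sessions = NULL, n_options = NULL,
                       n_shuffles = 1000, seed = 1) {
  tibble::tibble(
    b_index = b_index(labels, n_options = n_options),
    p_index = p_index(labels, sessions, n_shuffles, seed),
    n_shuffles = n_shuffles,
    seed = seed
  )
}

#' Conditional probability of continuing a run
#'
#' For each preceding-run length L, the probability that the next choice
#' repeats the current one given that the current run already contains
#' exactly L identical choices, pooled over the sequence. Transitions across
#' session boundaries are not counted. Lengths with no observations are
#' reported with `NA` probability, not imputed. For an iid chooser over N
#' options the curve is flat at 1/N.
#'
#' @param labels Label sequence.
#' @param sessions Optional session index.
#' @param max_length Largest preceding-run length reported (default: largest
#'   observed).
#' @return A tibble with columns `preceding` (L), `n` (opportunities),
#'   `continued`, `p`.
#' @export
continue_probability <- function(labels, sessions = NULL, max_length = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop_attnrl("empty sequence", "attnrl_invalid_input")
  if (is.null(sessions)) sessions <- rep(1L, length(labels))
  cont <- integer(0); prec <- integer(0)
  for (y in split(labels, sessions)) {
    if (length(y) < 2) next
    run_len <- integer(length(y))
    run_len[1] <- 1L
    for (t in 2:length(y)) {
      run_len[t] <- if (y[t] == y[t - 1]) run_len[t - 1] + 1L else 1L
    }
    idx <- seq_len(length(y) - 1)
    prec <- c(prec, run_len[idx])
    cont <- c(cont, as.integer(y[idx + 1] == y[idx]))
  }
  max_length <- max_length %||% if (length(prec)) max(prec) else 1L
  purrr::map_dfr(seq_len(max_length), function(L) {
    sel <- prec == L
    tibble::tibble(preceding = L, n = sum(sel), continued = sum(cont[sel]),
                   p = if (sum(sel) > 0) sum(cont[sel]) / sum(sel) else NA_real_)
  })
}

#' Chi-squared test of uniform category use
#'
#' Pearson goodness-of-fit statistic of observed counts against equal
#' expected counts, df = categories - 1.
#'
#' @param counts Nonnegative counts per category, total > 0.
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chi2_uniform(c(0.099, 0.266, 0.585, 0.049) * 1500)
#' @export
chi2_uniform <- function(counts) {
  counts <- as_counts(counts)
  if (sum(counts) <= 0) stop_attnrl("counts must have a positive total", "attnrl_invalid_input")
  ht <- suppressWarnings(chisq.test(counts))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' Entropy in consecutive trial windows
#'
#' Shannon entropy of the choice frequencies in non-overlapping windows of
#' `window` trials, computed within sessions; a trailing window shorter than
#' `window` is reported and flagged as partial.
#'
#' @param labels Label sequence.
#' @param sessions Optional session index.
#' @param window Window size in trials (default 50, >= 2).
#' @return A tibble with columns `session`, `window`, `n_trials`, `entropy`,
#'   `partial`.
#' @export
windowed_entropy <- function(labels, sessions = NULL, window = 50) {
  if (window < 2) stop_attnrl("window must be >= 2", "attnrl_invalid_input")
  labels <- as.character(labels)
  if (is.null(sessions)) sessions <- rep(1L, length(labels))
  win_size <- window
  purrr::map_dfr(split(labels, sessions), function(y) {
    idx <- ceiling(seq_along(y) / win_size)
    purrr::map_dfr(unique(idx), function(wi) {
      yy <- y[idx == wi]
      tibble::tibble(window = wi, n_trials = length(yy),
                     entropy = choice_entropy(table(yy)),
                     partial = length(yy) < win_size)
    })
  }, .id = "session") |>
    dplyr::mutate(session = as.integer(.data$session))
}

#' Session-wise area-statistic comparison against a reference
#'
#' For each session, the empirical sequence's mean area statistic against
#' `n_shuffles` random permutations is compared with the mean area statistic
#' of a reference sequence (one extra random permutation, or the session's
#' sorted sequence) against the same permutations; a paired t-test across
#' sessions then asks whether the empirical sequences deviate from the
#' reference more than a history-free sequence would. With
#' `scope = "overall"` the whole concatenated sequence is analysed as a
#' single unit (no t-test).
#'
#' @param labels Label sequence.
#' @param sessions Per-trial session index (>= 2 sessions for
#'   `scope = "session"`).
#' @param reference `"shuffled"` or `"sorted"`.
#' @param n_shuffles Permutations per session (default 1000).
#' @param seed Integer seed.
#' @param scope `"session"` (default) or `"overall"`.
#' @return For `scope = "session"`: a list of class `"area_test"` with the
#'   per-session tibble (`session`, `area_emp`, `area_ref`), `statistic`,
#'   `df`, `p_value`. For `scope = "overall"`: a one-row tibble with
#'   `area_emp` and `area_ref`.
#' @export
area_significance <- function(labels, sessions,
                              reference = c("shuffled", "sorted"),
                              n_shuffles = 1000, seed = 1,
                              scope = c("session", "overall")) {
  reference <- match.arg(reference)
  scope <- match.arg(scope)
  labels <- as.character(labels)
  set.seed(seed)
  one_unit <- function(y, brk = NULL) {
    emp <- extract_runs(y, brk)
    ref_seq <- if (reference == "sorted") sorted_reference(y) else sample(y)
    ref <- extract_runs(ref_seq, brk)
    a_emp <- a_ref <- numeric(n_shuffles)
    for (j in seq_len(n_shuffles)) {
      shuf <- extract_runs(sample(y), brk)
      xmax <- max(emp, ref, shuf)
      pshuf <- ccdf_grid(shuf, xmax)
      a_emp[j] <- area_grid(ccdf_grid(emp, xmax), pshuf)
      a_ref[j] <- area_grid(ccdf_grid(ref, xmax), pshuf)
    }
    c(area_emp = mean(a_emp), area_ref = mean(a_ref))
  }
  if (scope == "overall") {
    res <- one_unit(labels, sessions)
    return(tibble::tibble(area_emp = res[["area_emp"]], area_ref = res[["area_ref"]]))
  }
  units <- split(labels, sessions)
  if (length(units) < 2) {
    stop_attnrl("session-wise comparison needs at least 2 sessions", "attnrl_invalid_input")
  }
  per <- purrr::map_dfr(units, function(y) tibble::as_tibble(as.list(one_unit(y))),
                        .id = "session")
  d <- per$area_emp - per$area_ref
  if (stats::sd(d) == 0) {
    # degenerate paired differences: identical areas give t = 0, a constant
    # nonzero shift an infinite t
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    ht <- list(statistic = c(t = tval), parameter = c(df = nrow(per) - 1),
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    ht <- t.test(per$area_emp, per$area_ref, paired = TRUE)
  }
  structure(
    list(sessions = per,
         statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = unname(ht$p.value),
         reference = reference, n_shuffles = n_shuffles, seed = seed),
    class = "area_test"
  )
}

#' @export
print.area_test <- function(x, ...) {
  cat(sprintf("<area_test> empirical vs %s reference, %d sessions, %d shuffles\n",
              x$reference, nrow(x$sessions), x$n_shuffles))
  cat(sprintf("  paired t = %.3f, df = %d, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Summary metrics of a trial log
#'
#' Convenience wrapper computing the standard report for one trial log on one
#' attribute dimension: bias and persistence indices, the run-length table,
#' continuation probabilities, and the location-uniformity chi-squared test.
#'
#' @param log A trial log.
#' @param dimension `"item"` or `"location"` (default: the spec's most
#'   contributing dimension).
#' @param n_shuffles,seed Passed to [p_index()].
#' @return A list with elements `indices` (tibble), `runs`
#'   ([run_distribution()]), `continuation` (tibble), `chi2_location`
#'   (tibble).
#' @export
sequence_report <- function(log, dimension = NULL, n_shuffles = 1000, seed = 1) {
  labels <- choice_labels(log, dimension)
  pi_val <- tryCatch(
    p_index(labels, sessions = log$session, n_shuffles = n_shuffles, seed = seed),
    attnrl_undefined_index = function(e) NA_real_
  )
  list(
    indices = tibble::tibble(
      b_index = b_index(labels, n_options = 4),
      p_index = pi_val, n_shuffles = n_shuffles, seed = seed
    ),
    runs = run_distribution(labels, sessions = log$session),
    continuation = continue_probability(labels, sessions = log$session),
    chi2_location = chi2_uniform(table(factor(log$chosen_location,
                                              levels = unique(log$chosen_location))))
  )
}
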
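# internal: turn a trial log + spec into the arrays the likelihood needs.
# The per-session item-to-location assignment is taken from the log's
# "assignment" attribute when present; otherwise it is reconstructed from the
# observed (location, item) pairs of each session (possible whenever at least
# three of the four pairings were observed).
log_arrays <- function(log, spec) {
  stopifnot(inherits(spec, "condition_spec"))
  bad_loc <- setdiff(unique(log$chosen_location), spec$locations)
  if (length(bad_loc)) {
    stop_attnrl(sprintf("location label(s) outside the spec's option set: %s",
                        paste(bad_loc, collapse = ", ")), "attnrl_invalid_input")
  }
  bad_item <- setdiff(unique(log$item_label), spec$items)
  if (length(bad_item)) {
    stop_attnrl(sprintf("item label(s) outside the spec's option set: %s",
                        paste(bad_item, collapse = ", ")), "attnrl_invalid_input")
  }
  sessions <- sort(unique(log$session))
  n <- length(spec$locations)
  assignment <- attr(log, "assignment")
  item_at_loc <- matrix(NA_integer_, nrow = max(sessions), ncol = n)
  if (!is.null(assignment)) {
    for (s in sessions) {
      rows <- assignment[assignment$session == s, ]
      item_at_loc[s, match(rows$location, spec$locations)] <- match(rows$item, spec$items)
    }
  } else {
    for (s in sessions) {
      seen <- unique(log[log$session == s, c("chosen_location", "item_label")])
      li <- match(seen$chosen_location, spec$locations)
      ii <- match(seen$item_label, spec$items)
      if (anyDuplicated(li) || anyDuplicated(ii)) {
        stop_attnrl(sprintf("session %d: inconsistent item/location pairs", s),
                    "attnrl_invalid_input")
      }
      item_at_loc[s, li] <- ii
      if (sum(!is.na(item_at_loc[s, ])) == n - 1) {
        item_at_loc[s, which(is.na(item_at_loc[s, ]))] <-
          setdiff(seq_len(n), item_at_loc[s, !is.na(item_at_loc[s, ])])
      }
      if (anyNA(item_at_loc[s, ])) {
        stop_attnrl(sprintf(
          "session %d: cannot reconstruct the item-to-location assignment from the log; supply it via the log's 'assignment' attribute", s),
          "attnrl_invalid_input")
      }
    }
  }
  list(
    chosen = match(log$chosen_location, spec$locations) - 1L,
    session = as.integer(log$session),
    item_at_loc = item_at_loc - 1L
  )
}

#' Negative log-likelihood of a choice sequence
#'
#' Deterministically replays a trial log under the model: at each trial the
#' softmax choice probabilities are computed from the current action values,
#' `-log P(actual choice)` is accumulated (probabilities floored at
#' `params$prob_floor`), and the values are then updated using the
#' actually-chosen option. Action values carry across session boundaries by
#' default.
#'
#' @param log A trial log (from [simulate_choices()] or [read_trial_log()]).
#' @param spec The [condition_spec()] the log was recorded under.
#' @param params A [model_params()].
#' @param variant `"Qcu"` or `"Qc"` (no unchosen decay).
#' @param reset_sessions Reset action values at session boundaries.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation built from the exported update primitives; used for
#'   cross-validation).
#' @return The negative log-likelihood (a single nonnegative number).
#' @export
negative_log_likelihood <- function(log, spec, params,
                                    variant = c("Qcu", "Qc"),
                                    reset_sessions = FALSE,
                                    engine = c("cpp", "r")) {
  variant <- match.arg(variant)
  engine <- match.arg(engine)
  arr <- model_arrays(spec, params)
  la <- log_arrays(log, spec)
  if (engine == "cpp") {
    sum(nll_trials_cpp(
      la$chosen, la$session, la$item_at_loc,
      arr$x, arr$is_item, arr$w,
      params$alpha_c, params$mu, params$beta, params$gamma,
      params$reward_norm, params$q_floor, params$prob_floor,
      arr$q0, variant == "Qcu", reset_sessions
    ))
  } else {
    nll_replay_r(la, arr, params, variant, reset_sessions)
  }
}

# reference replay in plain R, built from the exported model primitives
nll_replay_r <- function(la, arr, params, variant, reset_sessions) {
  q <- arr$q0
  n <- ncol(q)
  nll <- 0
  prev_s <- la$session[1]
  for (t in seq_along(la$chosen)) {
    s <- la$session[t]
    if (reset_sessions && s != prev_s) q <- arr$q0
    prev_s <- s
    lev <- matrix(rep(seq_len(n), each = nrow(q)), nrow = nrow(q))
    lev[arr$is_item, ] <- matrix(la$item_at_loc[s, ] + 1L, nrow = sum(arr$is_item),
                                 ncol = n, byrow = TRUE)
    qi <- vapply(seq_len(n), function(l) sum(arr$w * q[cbind(seq_len(nrow(q)), lev[, l])]),
                 numeric(1))
    p <- choice_probabilities(qi, params$beta)
    ch <- la$chosen[t] + 1L
    nll <- nll - log(max(p[ch], params$prob_floor))
    for (k in seq_len(nrow(q))) {
      ck <- lev[k, ch]
      q[k, ] <- update_q_row(q[k, ], ck, arr$r[k, ck], params, variant)
    }
  }
  nll
}

#' Information criteria for a fitted choice model
#'
#' `AIC = 2 nll + 2 k`; `BIC = 2 nll + k log(n_trials)`; the likelihood-based
#' pseudo-R2 is `1 - nll / (n_trials * log(n_options))`, the improvement over
#' uniform random choice (0 for a chance-level model, 1 for a perfect one).
#'
#' @param nll Negative log-likelihood.
#' @param k_params Number of free parameters.
#' @param n_trials Number of trials.
#' @param n_options Number of options (for the chance likelihood).
#' @return A one-row tibble with `aic`, `bic`, `pseudo_r2`.
#' @examples
#' information_criteria(574.0, k_params = 4, n_trials = 1500)
#' @export
information_criteria <- function(nll, k_params, n_trials, n_options = 4) {
  if (n_trials < 1) stop_attnrl("n_trials must be >= 1", "attnrl_invalid_input")
  tibble::tibble(
    aic = 2 * nll + 2 * k_params,
    bic = 2 * nll + k_params * log(n_trials),
    pseudo_r2 = 1 - nll / (n_trials * log(n_options))
  )
}

#' Default parameter bounds for fitting
#' @return A named list of `c(lower, upper)` pairs for `alpha_c`, `mu`,
#'   `beta`, `gamma`.
#' @export
default_bounds <- function() {
  list(alpha_c = c(1e-3, 1), mu = c(0.1, 5), beta = c(0, 100), gamma = c(1e-3, 5))
}

#' Fit the choice model by maximum likelihood
#'
#' Bounded multi-start minimization of [negative_log_likelihood()] over the
#' free parameters (`alpha_c`, `mu`, `beta`, `gamma`; `mu` is fixed at 1 and
#' dropped for the `"Qc"` variant, which has no unchosen decay). Start points
#' are a seeded Latin hypercube over the bounds; each start is refined with
#' L-BFGS-B and the best endpoint is returned with all restart endpoints
#' logged. Deterministic given `seed`.
#'
#' @param log A trial log.
#' @param spec The condition the log was recorded under.
#' @param variant `"Qcu"` (4 free parameters) or `"Qc"` (3).
#' @param n_restarts Number of optimizer starts (default 10).
#' @param seed Integer seed for the start points.
#' @param bounds Named list of `c(lower, upper)` per parameter, see
#'   [default_bounds()].
#' @param config A [model_params()] supplying the fixed configuration
#'   (threshold angle, Q initialization, floors). Defaults to the generating
#'   parameters attached to the log when present, else to [model_params()]
#'   defaults with `q_init = 0`.
#' @param reset_sessions Passed to the likelihood.
#' @return An object of class `"choice_fit"`: a list with the fitted
#'   parameters (`params`), `nll`, `aic`, `bic`, `pseudo_r2`, `n_trials`,
#'   `k_params`, `variant`, `converged`, `seed` and a `restarts` tibble.
#'   Supports [tidy()], [glance()] and `print()`.
#' @export
fit_choice_model <- function(log, spec, variant = c("Qcu", "Qc"),
                             n_restarts = 10, seed = 1,
                             bounds = default_bounds(),
                             config = NULL,
                             reset_sessions = FALSE) {
  variant <- match.arg(variant)
  config <- config %||% attr(log, "params") %||%
    model_params(alpha_c = 0.5, mu = 1, beta = 1, gamma = 1)
  arr <- model_arrays(spec, config)
  la <- log_arrays(log, spec)
  free <- if (variant == "Qcu") c("alpha_c", "mu", "beta", "gamma") else
    c("alpha_c", "beta", "gamma")
  lower <- vapply(bounds[free], `[`, numeric(1), 1)
  upper <- vapply(bounds[free], `[`, numeric(1), 2)

  q0_for <- function(gamma) {
    if (identical(config$q_init, "informed")) {
      config$reward_norm * arr$x^gamma
    } else {
      matrix(config$q_init, nrow = nrow(arr$x), ncol = ncol(arr$x))
    }
  }
  objective <- function(par) {
    p <- as.list(setNames(par, free))
    mu <- p$mu %||% 1
    sum(nll_trials_cpp(
      la$chosen, la$session, la$item_at_loc,
      arr$x, arr$is_item, arr$w,
      p$alpha_c, mu, p$beta, p$gamma,
      config$reward_norm, config$q_floor, config$prob_floor,
      q0_for(p$gamma), variant == "Qcu", reset_sessions
    ))
  }

  set.seed(seed)
  starts <- lhs::randomLHS(n_restarts, length(free))
  starts <- sweep(sweep(starts, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(starts) <- free

  runs <- purrr::map(seq_len(n_restarts), function(i) {
    res <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    tibble::tibble(
      restart = i, nll = res$value, convergence = res$convergence,
      !!!setNames(as.list(res$par), free)
    )
  })
  runs <- dplyr::bind_rows(runs)
  if (nrow(runs) == 0) {
    stop_attnrl("all optimizer restarts failed", "attnrl_fit_failure")
  }
  best <- runs[which.min(runs$nll), ]
  est <- as.numeric(best[free])
  names(est) <- free
  fitted_params <- model_params(
    alpha_c = est[["alpha_c"]],
    mu = if (variant == "Qcu") est[["mu"]] else 1,
    beta = est[["beta"]], gamma = est[["gamma"]],
    theta_threshold_deg = config$theta_threshold_deg,
    q_init = config$q_init, reward_norm = config$reward_norm,
    q_floor = config$q_floor, prob_floor = config$prob_floor
  )
  n_trials <- nrow(log)
  k <- length(free)
  ic <- information_criteria(best$nll, k, n_trials, length(spec$locations))
  structure(
    list(
      params = fitted_params, estimate = est, variant = variant,
      nll = best$nll, aic = ic$aic, bic = ic$bic, pseudo_r2 = ic$pseudo_r2,
      n_trials = n_trials, k_params = k, n_restarts = n_restarts,
      converged = any(runs$convergence == 0), seed = seed, restarts = runs
    ),
    class = "choice_fit"
  )
}

#' Compare the chosen+unchosen and chosen-only model variants
#'
#' Fits both variants to the same trial log and compares them by BIC (ties
#' favour the model with fewer parameters).
#'
#' @inheritParams fit_choice_model
#' @return An object of class `"model_comparison"`: a tibble with one row per
#'   variant (`variant`, `k_params`, `nll`, `aic`, `bic`, `pseudo_r2`) plus
#'   attributes `favored` and `fits`.
#' @export
compare_models <- function(log, spec, seed = 1, n_restarts = 10,
                           config = NULL, reset_sessions = FALSE) {
  fits <- list(
    Qcu = fit_choice_model(log, spec, "Qcu", n_restarts, seed, config = config,
                           reset_sessions = reset_sessions),
    Qc  = fit_choice_model(log, spec, "Qc", n_restarts, seed, config = config,
                           reset_sessions = reset_sessions)
  )
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(variant = f$variant, k_params = f$k_params, nll = f$nll,
                   aic = f$aic, bic = f$bic, pseudo_r2 = f$pseudo_r2)
  })
  ord <- order(tab$bic, tab$k_params)
  structure(tab[ord, ],
            favored = tab$variant[ord][1],
            fits = fits,
            class = c("model_comparison", class(tab)))
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("<choice_fit> variant %s (%d free parameters), %d trials\n",
              x$variant, x$k_params, x$n_trials))
  cat("  ", paste(sprintf("%s = %.3f", names(x$estimate), x$estimate),
                  collapse = ", "), "\n")
  cat(sprintf("  nll %.1f | AIC %.1f | BIC %.1f | pseudo-R2 %.3f | converged: %s\n",
              x$nll, x$aic, x$bic, x$pseudo_r2, x$converged))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> favored by BIC: %s\n", attr(x, "favored")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @rdname fit_choice_model
#' @param x A `choice_fit`.
#' @param ... Unused.
#' @export
tidy.choice_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @rdname fit_choice_model
#' @export
glance.choice_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, nll = x$nll, aic = x$aic, bic = x$bic,
    pseudo_r2 = x$pseudo_r2, n_trials = x$n_trials, k_params = x$k_params,
    n_restarts = x$n_restarts, converged = x$converged
  )
}

#' @export
tidy.model_comparison <- function(x, ...) tibble::as_tibble(x)
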
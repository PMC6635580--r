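# internal: precompute the static arrays the model loop needs for a condition.
# x: K x n matrix of normalized attribute values per attribute level; item
# attributes are indexed by item, location attributes by location, so learned
# values follow the item identities across counterbalanced sessions.
model_arrays <- function(spec, params) {
  am <- attribute_matrix(spec)
  attrs <- names(spec$attributes)
  n <- length(spec$items)
  x <- matrix(NA_real_, nrow = length(attrs), ncol = n,
              dimnames = list(attrs, NULL))
  is_item <- logical(length(attrs))
  for (k in seq_along(attrs)) {
    a <- spec$attributes[[attrs[k]]]
    is_item[k] <- identical(a$type, "item")
    levels <- if (is_item[k]) spec$items else spec$locations
    rows <- am[am$attribute == attrs[k], ]
    x[k, ] <- rows$value[match(levels, rows$option)]
  }
  w_tbl <- attention_weights(preference_vector(am),
                             theta_threshold_deg = params$theta_threshold_deg)
  w <- w_tbl$weight[match(attrs, w_tbl$attribute)]
  r <- params$reward_norm * x^params$gamma
  q0 <- if (identical(params$q_init, "informed")) r else
    matrix(params$q_init, nrow = nrow(x), ncol = ncol(x), dimnames = dimnames(x))
  list(x = x, r = r, q0 = q0, w = w, is_item = is_item,
       mode = attr(w_tbl, "mode"), attrs = attrs)
}

#' Simulate a choice sequence from the model
#'
#' Forward-simulates trial-by-trial choices on a condition: attention weights
#' are computed once from the condition's choice-set geometry, each trial's
#' overall option values are the attention-weighted sums of the current
#' action values of the item and location occupying each compartment, the
#' choice is drawn from the softmax probabilities by inverse-CDF sampling,
#' and the action-value table is then updated (chosen levels toward their
#' subjective rewards, unchosen levels decaying at their memory-dependent
#' rates). Item-to-location assignments are re-drawn per session
#' (counterbalancing); action values carry across session boundaries unless
#' `reset_sessions = TRUE`.
#'
#' @param spec A [condition_spec()].
#' @param params A [model_params()].
#' @param n_trials Number of trials; defaults to the spec's
#'   `session_length * n_sessions`.
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#' @param variant `"Qcu"` (decay unchosen options) or `"Qc"` (chosen-only
#'   updates).
#' @param assignment Optional pre-built item-to-location table (as returned
#'   by [counterbalance_locations()]); drawn from the seeded RNG if `NULL`.
#' @param reset_sessions Reset action values to their initial values at each
#'   session boundary.
#' @param trace Also record per-trial choice probabilities and overall values
#'   (attached as attribute `"trace"`, a long tibble).
#' @return A tibble of class `"trial_log"` with columns `session`, `trial`
#'   (within session), `chosen_option` (item identity), `chosen_location` and
#'   `item_label` (same as `chosen_option`), and attributes `spec`, `params`,
#'   `seed`, `variant`, `assignment`.
#' @examples
#' log <- simulate_choices(builtin_condition(1), default_params(1),
#'                         n_trials = 300, seed = 42)
#' dplyr::count(log, chosen_option)
#' @export
simulate_choices <- function(spec, params, n_trials = NULL, seed,
                             variant = c("Qcu", "Qc"),
                             assignment = NULL,
                             reset_sessions = FALSE,
                             trace = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "condition_spec"), inherits(params, "model_params"))
  n_trials <- n_trials %||% (spec$session_length * spec$n_sessions)
  if (n_trials < 1) stop_attnrl("n_trials must be >= 1", "attnrl_invalid_input")
  set.seed(seed)
  n_sessions <- ceiling(n_trials / spec$session_length)
  if (is.null(assignment)) {
    assignment <- counterbalance_locations(spec, seed = NULL, n_sessions = n_sessions)
  }
  arr <- model_arrays(spec, params)
  n_opt <- length(spec$locations)
  # item index at each location, per session
  item_at_loc <- matrix(NA_integer_, nrow = n_sessions, ncol = n_opt)
  for (s in seq_len(n_sessions)) {
    rows <- assignment[assignment$session == s, ]
    item_at_loc[s, match(rows$location, spec$locations)] <- match(rows$item, spec$items)
  }
  q <- arr$q0
  session <- ((seq_len(n_trials) - 1L) %/% spec$session_length) + 1L
  trial <- ((seq_len(n_trials) - 1L) %% spec$session_length) + 1L
  chosen_loc <- integer(n_trials)
  chosen_item <- integer(n_trials)
  probs <- if (trace) matrix(NA_real_, n_trials, n_opt) else NULL
  vals <- if (trace) matrix(NA_real_, n_trials, n_opt) else NULL
  u <- runif(n_trials)
  for (t in seq_len(n_trials)) {
    s <- session[t]
    if (reset_sessions && t > 1 && s != session[t - 1]) q <- arr$q0
    # per-compartment level indices on each attribute
    lev <- matrix(rep(seq_len(n_opt), each = nrow(q)), nrow = nrow(q))
    lev[arr$is_item, ] <- matrix(item_at_loc[s, ], nrow = sum(arr$is_item),
                                 ncol = n_opt, byrow = TRUE)
    qi <- vapply(seq_len(n_opt), function(l) sum(arr$w * q[cbind(seq_len(nrow(q)), lev[, l])]),
                 numeric(1))
    p <- choice_probabilities(qi, params$beta)
    ch <- findInterval(u[t], cumsum(p), left.open = TRUE) + 1L
    chosen_loc[t] <- ch
    chosen_item[t] <- item_at_loc[s, ch]
    if (trace) { probs[t, ] <- p; vals[t, ] <- qi }
    for (k in seq_len(nrow(q))) {
      ck <- lev[k, ch]
      q[k, ] <- update_q_row(q[k, ], ck, arr$r[k, ck], params, variant)
    }
  }
  out <- tibble::tibble(
    session = session,
    trial = trial,
    chosen_option = spec$items[chosen_item],
    chosen_location = spec$locations[chosen_loc],
    item_label = spec$items[chosen_item]
  )
  attr(out, "spec") <- spec
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  attr(out, "variant") <- variant
  attr(out, "assignment") <- assignment[assignment$session <= n_sessions, ]
  if (trace) {
    attr(out, "trace") <- tibble::tibble(
      session = rep(session, each = n_opt),
      trial = rep(trial, each = n_opt),
      option = rep(spec$locations, n_trials),
      value = as.vector(t(vals)),
      probability = as.vector(t(probs))
    )
  }
  class(out) <- c("trial_log", class(out))
  out
}

#' Extract the label sequence of a trial log on one attribute dimension
#'
#' @param log A trial log.
#' @param dimension `"item"` or `"location"`; `NULL` uses the spec's
#'   `index_attribute` when the log carries its spec, else `"item"`.
#' @return Character vector of per-trial labels.
#' @export
choice_labels <- function(log, dimension = NULL) {
  dimension <- dimension %||% {
    sp <- attr(log, "spec")
    if (!is.null(sp)) sp$index_attribute else "item"
  }
  switch(dimension,
    item = log$item_label,
    location = log$chosen_location,
    stop_attnrl("dimension must be 'item' or 'location'", "attnrl_invalid_input")
  )
}
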
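#' Construct a condition specification
#'
#' A condition spec describes the fixed choice context of one experimental
#' condition: four items presented in four tray compartments (locations LL,
#' ML, MR, RR), with item-to-location assignment counterbalanced across
#' sessions. Each attribute attaches either to the item identity (calorie,
#' colour value) or to the location (proximity = 1/distance), which is where
#' its action values live across sessions.
#'
#' @param condition Integer condition id (free-form for custom specs).
#' @param items Character vector of item labels.
#' @param attributes Named list; each element is
#'   `list(type = "item"|"location", values = <named numeric>)` with raw
#'   attribute values per item or per location.
#' @param locations Location labels, default `c("LL","ML","MR","RR")`.
#' @param distances_cm Distances from the subject to each location.
#' @param session_length,n_sessions Trials per session and session count.
#' @param theta_threshold_deg Attention gate threshold (degrees).
#' @param normalization Attribute normalization scheme, see
#'   [normalize_attributes()].
#' @param index_attribute Which attribute dimension (`"item"` or
#'   `"location"`) sequence indices are reported on by default - the most
#'   choice-contributing dimension of the condition.
#' @return A list of class `"condition_spec"`.
#' @export
condition_spec <- function(condition, items, attributes,
                           locations = c("LL", "ML", "MR", "RR"),
                           distances_cm = c(18, 15, 15, 18),
                           session_length = 150, n_sessions = 10,
                           theta_threshold_deg = 30,
                           normalization = "max",
                           index_attribute = "item") {
  if (length(items) != length(locations)) {
    stop_attnrl("need as many items as locations", "attnrl_invalid_config")
  }
  for (nm in names(attributes)) {
    a <- attributes[[nm]]
    levels <- if (identical(a$type, "item")) items else locations
    if (!identical(a$type, "item") && !identical(a$type, "location")) {
      stop_attnrl(sprintf("attribute '%s': type must be 'item' or 'location'", nm),
                  "attnrl_invalid_config")
    }
    if (is.null(names(a$values))) names(attributes[[nm]]$values) <- levels
    if (!setequal(names(attributes[[nm]]$values), levels)) {
      stop_attnrl(sprintf("attribute '%s': values must cover all %ss", nm, a$type),
                  "attnrl_invalid_config")
    }
    attributes[[nm]]$values <- attributes[[nm]]$values[levels]
  }
  structure(
    list(
      condition = condition, items = items, locations = locations,
      distances_cm = distances_cm, attributes = attributes,
      session_length = session_length, n_sessions = n_sessions,
      theta_threshold_deg = theta_threshold_deg,
      normalization = normalization,
      index_attribute = index_attribute
    ),
    class = "condition_spec"
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition_spec> condition %s: %d items x %d locations, %d x %d trials\n",
              x$condition, length(x$items), length(x$locations),
              x$n_sessions, x$session_length))
  print(attribute_matrix(x), ...)
  invisible(x)
}

#' Built-in experimental conditions
#'
#' The three conditions of the four-option foraging task. Condition 1: four
#' different foods (PN, FG, PL, KR) whose calorie contents per piece are
#' 2.06, 0.78, 0.15 and 0.08 kcal, plus location proximity (reciprocal of the
#' 18, 15, 15, 18 cm distances to LL, ML, MR, RR). Condition 2: four
#' identically sized foods in different colours; colour has no physical value
#' scale, so ground-truth colour values are supplied (defaults below) and
#' [matching_law_values()] can estimate them from choice rates instead.
#' Condition 3: four identical pellets (0.15 kcal each), leaving location the
#' only distinctive attribute. `variant = "PN"` gives the alternate Condition
#' 3 in which the pellets are replaced by peanut halves (2.06 kcal), used for
#' one subject in the original task; it is not part of the default
#' three-condition battery.
#'
#' @param condition 1, 2 or 3.
#' @param color_values Ground-truth colour values for Condition 2 (named or in
#'   order red, green, orange, purple).
#' @param variant For condition 3: `"PL"` (default) or `"PN"`.
#' @return A [condition_spec()].
#' @examples
#' builtin_condition(1)
#' @export
builtin_condition <- function(condition,
                              color_values = c(red = 1.0, green = 0.7, orange = 0.5, purple = 0.4),
                              variant = c("PL", "PN")) {
  variant <- match.arg(variant)
  if (!condition %in% 1:3) {
    stop_attnrl("unknown condition id (must be 1, 2 or 3)", "attnrl_invalid_config")
  }
  proximity <- list(type = "location",
                    values = c(LL = 1 / 18, ML = 1 / 15, MR = 1 / 15, RR = 1 / 18))
  if (condition == 1) {
    condition_spec(
      condition = 1,
      items = c("PN", "FG", "PL", "KR"),
      attributes = list(
        calorie = list(type = "item",
                       values = c(PN = 2.06, FG = 0.78, PL = 0.15, KR = 0.08)),
        proximity = proximity
      ),
      index_attribute = "item"
    )
  } else if (condition == 2) {
    items <- c("red", "green", "orange", "purple")
    if (is.null(names(color_values))) names(color_values) <- items
    condition_spec(
      condition = 2,
      items = items,
      attributes = list(
        color = list(type = "item", values = color_values),
        proximity = proximity
      ),
      index_attribute = "location"
    )
  } else {
    kcal <- if (variant == "PL") 0.15 else 2.06
    items <- paste0(variant, "_", 1:4)
    condition_spec(
      condition = 3,
      items = items,
      attributes = list(
        calorie = list(type = "item", values = setNames(rep(kcal, 4), items)),
        proximity = proximity
      ),
      index_attribute = "location"
    )
  }
}

#' Normalized attribute table of a condition
#'
#' Expands a condition spec into the long attribute-by-option table used by
#' the choice-set geometry ([preference_vector()], [attention_weights()]),
#' normalized with the spec's scheme.
#'
#' @param spec A [condition_spec()].
#' @return A tibble with columns `attribute`, `level_type`, `option`, `raw`,
#'   `value`.
#' @export
attribute_matrix <- function(spec) {
  stopifnot(inherits(spec, "condition_spec"))
  raw <- purrr::imap_dfr(spec$attributes, function(a, nm) {
    tibble::tibble(
      attribute = nm,
      level_type = a$type,
      option = names(a$values),
      raw = unname(a$values)
    )
  })
  norm <- normalize_attributes(raw[c("attribute", "option", "raw")],
                               scheme = spec$normalization)
  dplyr::left_join(raw, norm[c("attribute", "option", "value")],
                   by = c("attribute", "option")) |>
    dplyr::arrange(match(.data$attribute, names(spec$attributes)))
}

#' Condition attention weights
#'
#' Convenience wrapper: geometry of the full option set of a condition,
#' passed through the attention gate. Constant within a condition, since the
#' choice set does not change across its sessions.
#'
#' @param spec A [condition_spec()].
#' @return An [attention_weights()] tibble.
#' @export
condition_weights <- function(spec) {
  attention_weights(preference_vector(attribute_matrix(spec)),
                    theta_threshold_deg = spec$theta_threshold_deg)
}

#' Counterbalanced item-to-location assignments
#'
#' One permutation of items over locations per session. The default scheme
#' draws independent seeded permutations, re-drawing any that exactly repeats
#' the previous session's arrangement. `balanced = TRUE` instead cycles
#' through randomly generated Latin squares, so over any 4k sessions every
#' item occupies every location exactly k times.
#'
#' @param spec A [condition_spec()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param n_sessions Number of sessions (defaults to the spec's).
#' @param balanced Use the Latin-square balanced scheduler.
#' @return A tibble with columns `session`, `location`, `item`.
#' @export
counterbalance_locations <- function(spec, seed = NULL,
                                     n_sessions = spec$n_sessions,
                                     balanced = FALSE) {
  stopifnot(inherits(spec, "condition_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(spec$items)
  perms <- vector("list", n_sessions)
  if (balanced) {
    s <- 1
    while (s <= n_sessions) {
      base <- sample(n)               # random first row
      rows <- sample(n)               # random row order of the cyclic square
      for (r in rows) {
        if (s > n_sessions) break
        perms[[s]] <- base[((seq_len(n) + r - 2) %% n) + 1]
        s <- s + 1
      }
    }
  } else {
    prev <- NULL
    for (s in seq_len(n_sessions)) {
      p <- sample(n)
      while (!is.null(prev) && identical(p, prev)) p <- sample(n)
      perms[[s]] <- p
      prev <- p
    }
  }
  purrr::imap_dfr(perms, function(p, s) {
    tibble::tibble(session = s, location = spec$locations,
                   item = spec$items[p])
  })
}

#' Relative values from choice rates via the matching law
#'
#' Under the matching law, response allocation is proportional to relative
#' reinforcement value; read in reverse, relative values are proportional to
#' observed choice rates. Values are scaled so the maximum is 1, consistent
#' with divide-by-max attribute normalization. Used to assign a value scale
#' to attributes with no physical one (colour).
#'
#' @param choice_rates Nonnegative choice rates (roughly summing to 1), named
#'   or unnamed.
#' @return Values proportional to the rates, max 1.
#' @examples
#' matching_law_values(c(0.5, 0.25, 0.125, 0.125))
#' @export
matching_law_values <- function(choice_rates) {
  if (any(choice_rates < 0) || sum(choice_rates) <= 0) {
    stop_attnrl("choice rates must be nonnegative with a positive sum", "attnrl_invalid_input")
  }
  choice_rates / max(choice_rates)
}

#' Reference parameter sets for the built-in conditions
#'
#' Per-condition parameter sets (group means of maximum-likelihood estimates
#' on the original task): Condition 1 `alpha_c` 0.79, `mu` 2.82, `beta`
#' 20.50, `gamma` 0.09; Condition 2 0.90, 2.05, 12.37, 0.21; Condition 3
#' 0.60, 2.51, 20.87, 0.94. Returned with informed Q initialization, the
#' generator's default for synthetic subjects (options are in full view from
#' trial one), and with the calibrated subjective-value scale
#' `reward_norm = 0.29`. The value scale is not identifiable from fitting (it
#' is absorbed by `beta`), but jointly with the `beta` values above it sets
#' the forward-simulation regime; it was calibrated once against the two
#' printed bias-index anchors of the original task (Condition 1: 0.460,
#' Condition 3: 0.247) and is frozen. See the methods vignette.
#'
#' @param condition 1, 2 or 3.
#' @param q_init Initialization passed through to [model_params()].
#' @param reward_norm Subjective-value scale passed through to
#'   [model_params()].
#' @return A [model_params()].
#' @export
default_params <- function(condition, q_init = "informed", reward_norm = 0.29) {
  tab <- list(
    `1` = c(alpha_c = 0.79, mu = 2.82, beta = 20.50, gamma = 0.09),
    `2` = c(alpha_c = 0.90, mu = 2.05, beta = 12.37, gamma = 0.21),
    `3` = c(alpha_c = 0.60, mu = 2.51, beta = 20.87, gamma = 0.94)
  )[[as.character(condition)]]
  if (is.null(tab)) stop_attnrl("unknown condition id", "attnrl_invalid_config")
  model_params(alpha_c = tab[["alpha_c"]], mu = tab[["mu"]],
               beta = tab[["beta"]], gamma = tab[["gamma"]],
               q_init = q_init, reward_norm = reward_norm)
}

#' Generate a synthetic subject
#'
#' Simulates a full subject on a built-in (or custom) condition: a seeded
#' 1,500-trial choice sequence with the condition's session structure and
#' counterbalanced item locations.
#'
#' @param condition Condition id (1-3) or a [condition_spec()].
#' @param params A [model_params()]; defaults to [default_params()] of the
#'   condition.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_choices()].
#' @return A trial-log tibble (see [simulate_choices()]) with the generating
#'   spec, params and seed attached as attributes.
#' @export
generate_subject <- function(condition, params = NULL, seed, ...) {
  spec <- if (inherits(condition, "condition_spec")) condition else builtin_condition(condition)
  if (is.null(params)) {
    params <- if (inherits(condition, "condition_spec")) {
      stop_attnrl("supply `params` with a custom condition_spec", "attnrl_invalid_config")
    } else {
      default_params(condition)
    }
  }
  simulate_choices(spec, params, seed = seed, ...)
}

#' Fixture choice sequences with known run-length laws
#'
#' Seeded generators of label sequences whose run-length distribution is
#' known in closed form, used to validate the sequence statistics:
#' `"iid"` draws uniformly (runs geometric with continuation probability
#' `1/n_options`, mean `1/(1 - 1/n_options)`); `"markov_stay"` repeats the
#' previous label with probability `parameter` and otherwise switches
#' uniformly (runs geometric with continuation `parameter`); `"sorted"` is an
#' iid draw sorted into one block per label; `"bursty"` is `markov_stay` with
#' a high default stay probability of 0.9.
#'
#' @param kind One of `"iid"`, `"markov_stay"`, `"sorted"`, `"bursty"`.
#' @param n Sequence length.
#' @param n_options Alphabet size.
#' @param parameter Stay probability for the Markov kinds.
#' @param seed Integer seed.
#' @param labels Label alphabet (default `LETTERS`).
#' @return A character vector of length `n`.
#' @export
fixture_sequences <- function(kind = c("iid", "markov_stay", "sorted", "bursty"),
                              n, n_options = 4, parameter = NULL, seed = 1,
                              labels = LETTERS[seq_len(n_options)]) {
  kind <- match.arg(kind)
  if (n < 1) stop_attnrl("n must be >= 1", "attnrl_invalid_input")
  set.seed(seed)
  if (kind == "iid") return(sample(labels, n, replace = TRUE))
  if (kind == "sorted") return(sort(sample(labels, n, replace = TRUE)))
  stay <- parameter %||% if (kind == "bursty") 0.9 else
    stop_attnrl("markov_stay needs `parameter` (the stay probability)", "attnrl_invalid_input")
  out <- character(n)
  out[1] <- sample(labels, 1)
  if (n > 1) {
    u <- runif(n - 1)
    for (t in 2:n) {
      out[t] <- if (u[t - 1] < stay) out[t - 1] else
        sample(setdiff(labels, out[t - 1]), 1)
    }
  }
  out
}
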
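#' Model parameters
#'
#' Bundles the four free parameters of the choice model with its fixed
#' configuration. The free parameters (estimated by [fit_choice_model()]) are:
#' `alpha_c`, the learning rate for the chosen option; `mu`, the exponent
#' making the unchosen-option decay rate memory-dependent
#' (`alpha_u = alpha_c * Q^(mu - 1)`, so `mu = 1` recovers a constant decay
#' rate); `beta`, the softmax inverse temperature; and `gamma`, the value
#' sensitivity exponent of the power-law subjective reward
#' `r = reward_norm * x^gamma`.
#'
#' Fixed configuration: `theta_threshold_deg`, the attention gate threshold
#' (degrees, default 30, kept below 45 so the selective winner is unique);
#' `q_init`, the initial action value (0, a number, or `"informed"` for
#' Q(0) = subjective reward, appropriate when the options are in full view
#' from the first trial); `reward_norm`, the normalizing constant N of the
#' subjective reward (default 1; any other value is absorbed by `beta` and so
#' not identifiable); `q_floor`, a small positive floor applied inside the
#' power `Q^(mu - 1)` (needed when `mu < 1` as Q approaches 0); and
#' `prob_floor`, the floor applied to choice probabilities before taking logs
#' in the likelihood.
#'
#' @param alpha_c Learning rate for chosen options, in \[0, 1\].
#' @param mu Decay exponent, > 0.
#' @param beta Softmax inverse temperature, >= 0.
#' @param gamma Value sensitivity exponent, > 0.
#' @param theta_threshold_deg Attention threshold angle in degrees.
#' @param q_init Initial action value (>= 0) or `"informed"`.
#' @param reward_norm Normalizing constant N of the subjective reward, > 0.
#' @param q_floor Numerical floor inside `Q^(mu - 1)`.
#' @param prob_floor Probability floor used by the likelihood.
#' @return A list of class `"model_params"`.
#' @examples
#' model_params(alpha_c = 0.79, mu = 2.82, beta = 20.5, gamma = 0.09)
#' @export
model_params <- function(alpha_c, mu, beta, gamma,
                         theta_threshold_deg = 30,
                         q_init = 0,
                         reward_norm = 1,
                         q_floor = 1e-8,
                         prob_floor = 1e-12) {
  chk <- function(ok, msg) if (!ok) stop_attnrl(msg, "attnrl_invalid_config")
  chk(is.numeric(alpha_c) && alpha_c >= 0 && alpha_c <= 1, "alpha_c must be in [0, 1]")
  chk(is.numeric(mu) && mu > 0, "mu must be > 0")
  chk(is.numeric(beta) && beta >= 0, "beta must be >= 0")
  chk(is.numeric(gamma) && gamma > 0, "gamma must be > 0")
  chk(is.numeric(reward_norm) && reward_norm > 0, "reward_norm must be > 0")
  chk(identical(q_init, "informed") || (is.numeric(q_init) && q_init >= 0),
      "q_init must be a nonnegative number or \"informed\"")
  structure(
    list(
      alpha_c = alpha_c, mu = mu, beta = beta, gamma = gamma,
      theta_threshold_deg = theta_threshold_deg,
      q_init = q_init, reward_norm = reward_norm,
      q_floor = q_floor, prob_floor = prob_floor
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  alpha_c = %g, mu = %g, beta = %g, gamma = %g\n",
              x$alpha_c, x$mu, x$beta, x$gamma))
  cat(sprintf("  theta_threshold = %g deg, q_init = %s, N = %g\n",
              x$theta_threshold_deg, paste(x$q_init), x$reward_norm))
  invisible(x)
}

#' Subjective reward of an attribute value
#'
#' Power-law mapping from a normalized attribute value to subjective reward,
#' `r = n_const * x^gamma`. `gamma < 1` compresses differences between
#' options (diminishing sensitivity), `gamma > 1` expands them.
#'
#' @param x Normalized attribute value(s) in (0, 1].
#' @param gamma Value sensitivity exponent, > 0.
#' @param n_const Normalizing constant N, > 0.
#' @return Subjective reward value(s), equal to `n_const` at `x = 1`.
#' @examples
#' subjective_reward(0.0388, gamma = 0.09)
#' @export
subjective_reward <- function(x, gamma, n_const = 1) {
  if (any(x <= 0)) stop_attnrl("attribute values must be positive", "attnrl_invalid_input")
  if (gamma <= 0 || n_const <= 0) {
    stop_attnrl("gamma and n_const must be positive", "attnrl_invalid_input")
  }
  n_const * x^gamma
}

#' Memory-dependent learning rate for unchosen options
#'
#' The decay rate of an unchosen option is proportional to a power of its own
#' action value: `alpha_u = alpha_c * Q^(mu - 1)`. High-valued options decay
#' fast, near-forgotten options barely change; `mu = 1` gives the constant
#' decay rate of standard models. The value is floored at `q_floor` inside the
#' power (the power diverges at 0 for `mu < 1`) and the result clamped to
#' \[0, 1\] so the decay remains a contraction.
#'
#' @param q Current action value(s), >= 0.
#' @param alpha_c Chosen-option learning rate.
#' @param mu Decay exponent.
#' @param q_floor Floor used inside the power.
#' @return Learning rate(s) in \[0, 1\]. Exactly `alpha_c` when `mu = 1`.
#'   A value of exactly 0 with `mu > 1` returns 0 (nothing left to forget).
#' @export
unchosen_learning_rate <- function(q, alpha_c, mu, q_floor = 1e-8) {
  if (mu == 1) return(rep(alpha_c, length(q)))
  base <- pmax(q, q_floor)
  rate <- alpha_c * base^(mu - 1)
  rate[q == 0 & mu > 1] <- 0
  pmin(pmax(rate, 0), 1)
}

#' One learning update of the action-value table
#'
#' Updates a Q table after a choice: on every attribute, the chosen option
#' moves toward its subjective reward at rate `alpha_c`
#' (`Q <- Q + alpha_c * (r - Q)`), and each unchosen option decays toward 0
#' at its memory-dependent rate [unchosen_learning_rate()]. Outputs are
#' clamped to be nonnegative. Pure: the input table is not modified.
#'
#' @param q Numeric matrix of action values, rows = attributes (named), cols
#'   = options (named).
#' @param chosen Chosen option: a column name or index.
#' @param rewards Named numeric vector of subjective rewards for the chosen
#'   option, one per attribute (row of `q`).
#' @param params A [model_params()].
#' @param variant `"Qcu"` (default: update chosen and decay unchosen) or
#'   `"Qc"` (update the chosen option only).
#' @return The updated Q matrix.
#' @export
update_q <- function(q, chosen, rewards, params, variant = c("Qcu", "Qc")) {
  variant <- match.arg(variant)
  if (!is.matrix(q)) stop_attnrl("`q` must be a matrix (attributes x options)", "attnrl_invalid_input")
  if (is.character(chosen)) chosen <- match(chosen, colnames(q))
  if (is.na(chosen) || chosen < 1 || chosen > ncol(q)) {
    stop_attnrl("`chosen` is not an option of the Q table", "attnrl_invalid_input")
  }
  if (!is.null(rownames(q))) {
    if (is.null(names(rewards)) || !all(rownames(q) %in% names(rewards))) {
      stop_attnrl("`rewards` must be named with one value per attribute of `q`",
                  "attnrl_invalid_input")
    }
    rewards <- rewards[rownames(q)]
  } else if (length(rewards) != nrow(q)) {
    stop_attnrl("`rewards` must have one value per attribute of `q`", "attnrl_invalid_input")
  }
  for (k in seq_len(nrow(q))) {
    q[k, ] <- update_q_row(q[k, ], chosen, rewards[[k]], params, variant)
  }
  q
}

# single-attribute update used by update_q() and the simulator
update_q_row <- function(qrow, chosen_idx, reward, params, variant = "Qcu") {
  qrow[chosen_idx] <- qrow[chosen_idx] + params$alpha_c * (reward - qrow[chosen_idx])
  if (variant == "Qcu") {
    u <- setdiff(seq_along(qrow), chosen_idx)
    a_u <- unchosen_learning_rate(qrow[u], params$alpha_c, params$mu, params$q_floor)
    qrow[u] <- qrow[u] + a_u * (0 - qrow[u])
  }
  pmax(qrow, 0)
}

#' Attention-weighted overall option values
#'
#' Integrates per-attribute action values into one overall value per option,
#' `Q_i = sum_k w_k * Q_{k,i}`.
#'
#' @param q Q matrix (attributes x options).
#' @param w An [attention_weights()] tibble, or a numeric vector of weights in
#'   row order of `q`.
#' @return Named numeric vector of overall values, one per option.
#' @export
overall_values <- function(q, w) {
  if (inherits(w, "attention_weights") || is.data.frame(w)) {
    if (!is.null(rownames(q))) {
      if (!setequal(w$attribute, rownames(q))) {
        stop_attnrl("attention weights and Q table cover different attributes",
                    "attnrl_invalid_input")
      }
      w <- w$weight[match(rownames(q), w$attribute)]
    } else {
      w <- w$weight
    }
  }
  if (length(w) != nrow(q)) {
    stop_attnrl("need one weight per attribute (row) of `q`", "attnrl_invalid_input")
  }
  drop(crossprod(q, w))[seq_len(ncol(q))] |> setNames(colnames(q))
}

#' Softmax choice probabilities
#'
#' Maps overall option values to choice probabilities,
#' `P_i = exp(beta * Q_i) / sum_j exp(beta * Q_j)`, computed with
#' max-subtraction so large `beta` cannot overflow. Invariant to adding a
#' constant to all values; `beta = 0` yields uniform probabilities.
#'
#' @param values Numeric vector of overall option values.
#' @param beta Inverse temperature, >= 0.
#' @return Probabilities summing to 1, names preserved.
#' @examples
#' choice_probabilities(c(1, 0), beta = 2)
#' @export
choice_probabilities <- function(values, beta) {
  if (any(!is.finite(values))) stop_attnrl("values must be finite", "attnrl_invalid_input")
  if (beta < 0) stop_attnrl("beta must be >= 0", "attnrl_invalid_input")
  z <- beta * values
  z <- z - max(z)
  p <- exp(z)
  p / sum(p)
}
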
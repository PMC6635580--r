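test_that("likelihood limits: uniform choice and first-trial uniformity", {
  spec <- builtin_condition(1)
  p0 <- model_params(alpha_c = 0.5, mu = 2, beta = 0, gamma = 0.5, q_init = 0)
  log <- simulate_choices(spec, p0, n_trials = 100, seed = 1)
  expect_equal(negative_log_likelihood(log, spec, p0), 100 * log(4),
               tolerance = 1e-10)
  one <- log[1, ]
  attr(one, "assignment") <- attr(log, "assignment")
  p <- model_params(alpha_c = 0.7, mu = 2, beta = 9, gamma = 0.5, q_init = 0)
  expect_equal(negative_log_likelihood(one, spec, p), log(4), tolerance = 1e-10)
})

test_that("a three-trial sequence matches the hand-unrolled likelihood", {
  spec <- toy_spec_2opt()
  p <- model_params(alpha_c = 1, mu = 1, beta = 1, gamma = 1, q_init = 0)
  log <- toy_log(c("A", "A", "B"), spec)
  # trial 1: Q = (0,0), P(A) = 1/2
  # update: Q_A <- 1 (x_A = 1), Q_B stays 0
  # trial 2: P(A) = e/(e+1); no change (zero PE, zero value)
  # trial 3: P(B) = 1/(e+1)
  oracle <- log(2) + log(1 + exp(-1)) + log(1 + exp(1))
  expect_equal(negative_log_likelihood(log, spec, p, engine = "r"), oracle,
               tolerance = 1e-10)
  expect_equal(negative_log_likelihood(log, spec, p, engine = "cpp"), oracle,
               tolerance = 1e-10)
})

test_that("compiled and reference replays agree across conditions and variants", {
  for (cond in 1:3) {
    spec <- builtin_condition(cond)
    truth <- default_params(cond)
    log <- simulate_choices(spec, truth, n_trials = 450, seed = 70 + cond)
    for (variant in c("Qcu", "Qc")) {
      a <- negative_log_likelihood(log, spec, truth, variant = variant, engine = "cpp")
      b <- negative_log_likelihood(log, spec, truth, variant = variant, engine = "r")
      expect_equal(a, b, tolerance = 1e-10)
    }
    # session-reset configuration too
    a <- negative_log_likelihood(log, spec, truth, reset_sessions = TRUE)
    b <- negative_log_likelihood(log, spec, truth, reset_sessions = TRUE, engine = "r")
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under relabeling of options", {
  spec <- builtin_condition(1)
  p <- default_params(1)
  log <- simulate_choices(spec, p, n_trials = 300, seed = 81)
  ren <- setNames(paste0("item", 1:4), spec$items)
  spec2 <- spec
  spec2$items <- unname(ren[spec$items])
  names(spec2$attributes$calorie$values) <- unname(ren[names(spec$attributes$calorie$values)])
  log2 <- log
  log2$chosen_option <- unname(ren[log$chosen_option])
  log2$item_label <- unname(ren[log$item_label])
  asn <- attr(log, "assignment")
  asn$item <- unname(ren[asn$item])
  attr(log2, "assignment") <- asn
  expect_equal(negative_log_likelihood(log2, spec2, p),
               negative_log_likelihood(log, spec, p), tolerance = 1e-12)
})

test_that("generating parameters beat perturbed ones on their own data", {
  spec <- builtin_condition(1)
  truth <- default_params(1)
  logs <- purrr::map(1:3, function(s) simulate_choices(spec, truth, seed = 90 + s))
  mean_nll <- function(p) mean(purrr::map_dbl(logs, function(l)
    negative_log_likelihood(l, spec, p) / nrow(l)))
  base <- mean_nll(truth)
  set.seed(17)
  for (i in 1:20) {
    f <- runif(4, 0.5, 1.5)
    pert <- model_params(
      alpha_c = min(1, truth$alpha_c * f[1]),
      mu = truth$mu * f[2],
      beta = truth$beta * f[3],
      gamma = truth$gamma * f[4],
      q_init = truth$q_init, reward_norm = truth$reward_norm
    )
    expect_lte(base, mean_nll(pert) + 0.01)
  }
})

test_that("information criteria reproduce the fit-quality table arithmetic", {
  # all printed (-LL, AIC, BIC) cells, k = 4 for the chosen+unchosen variant,
  # k = 3 for chosen-only, n = 1500 trials
  cells <- tibble::tribble(
    ~nll,   ~k, ~aic,   ~bic,
    574.0,   4, 1155.8, 1177.0,
    922.2,   3, 1850.4, 1866.3,
    931.8,   4, 1871.7, 1893.0,
    1951.8,  3, 3909.6, 3925.5,
    829.6,   4, 1667.1, 1688.3,
    984.9,   3, 1975.6, 1991.6
  )
  for (i in seq_len(nrow(cells))) {
    ic <- information_criteria(cells$nll[i], cells$k[i], 1500)
    expect_equal(ic$aic, cells$aic[i], tolerance = 0.5 / cells$aic[i])
    expect_equal(ic$bic, cells$bic[i], tolerance = 0.5 / cells$bic[i])
  }
  expect_equal(information_criteria(574.0, 4, 1500)$pseudo_r2, 0.72, tolerance = 0.01)
  # chance-level parameters give pseudo-R2 exactly 0
  expect_equal(information_criteria(1500 * log(4), 4, 1500)$pseudo_r2, 0)
})

test_that("fitting is deterministic, nested and recovers structure", {
  spec <- builtin_condition(1)
  truth <- default_params(1)
  log <- simulate_choices(spec, truth, seed = 23)
  f1 <- fit_choice_model(log, spec, n_restarts = 4, seed = 2)
  f2 <- fit_choice_model(log, spec, n_restarts = 4, seed = 2)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$nll, f2$nll)
  expect_true(f1$converged)
  expect_lt(f1$nll, nrow(log) * log(4))  # beats chance

  # nesting: the richer model can always match the constant-decay special case
  p1 <- model_params(alpha_c = 0.6, mu = 1, beta = 6, gamma = 0.5,
                     q_init = "informed", reward_norm = 0.29)
  log_mu1 <- simulate_choices(spec, p1, seed = 24)
  fu <- fit_choice_model(log_mu1, spec, "Qcu", n_restarts = 6, seed = 3)
  fc <- fit_choice_model(log_mu1, spec, "Qc", n_restarts = 6, seed = 3)
  expect_lte(fu$nll, fc$nll + 0.5)
  expect_identical(fc$k_params, 3L)
  expect_identical(fu$k_params, 4L)

  # glance/tidy accessors
  expect_identical(tidy(fu)$term, c("alpha_c", "mu", "beta", "gamma"))
  expect_identical(tidy(fc)$term, c("alpha_c", "beta", "gamma"))
  g <- glance(fu)
  expect_equal(g$aic, 2 * g$nll + 2 * g$k_params)
  expect_equal(g$bic, 2 * g$nll + g$k_params * log(g$n_trials))
})

test_that("model comparison favours parsimony on equal likelihoods", {
  spec <- builtin_condition(1)
  truth <- default_params(1)
  log <- simulate_choices(spec, truth, n_trials = 600, seed = 25)
  cmp <- compare_models(log, spec, seed = 4, n_restarts = 4)
  expect_s3_class(cmp, "model_comparison")
  expect_true(attr(cmp, "favored") %in% c("Qcu", "Qc"))
  # penalty-only decision when the likelihoods tie
  ic4 <- information_criteria(500, 4, 600)
  ic3 <- information_criteria(500, 3, 600)
  expect_lt(ic3$bic, ic4$bic)
})

test_that("labels outside the option set are rejected with the label named", {
  spec <- builtin_condition(1)
  log <- simulate_choices(spec, default_params(1), n_trials = 50, seed = 26)
  bad <- log
  bad$item_label[3] <- "XX"
  expect_error(negative_log_likelihood(bad, spec, default_params(1)),
               regexp = "XX", class = "attnrl_invalid_input")
})
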
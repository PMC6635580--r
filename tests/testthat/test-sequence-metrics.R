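test_that("entropy and bias index match closed forms and printed rates", {
  expect_equal(choice_entropy(rep(25, 4)), log(4))
  expect_equal(choice_entropy(c(0, 0, 10, 0)), 0)
  # worked frequencies from the identical-items condition (printed rates sum
  # to 0.999; the entropy is taken over the renormalized frequencies)
  f <- c(0.099, 0.266, 0.585, 0.049)
  pf <- f / sum(f)
  expect_equal(choice_entropy(f), -sum(pf * log(pf)))
  expect_equal(choice_entropy(f), 1.0426, tolerance = 1e-4)
  expect_lt(abs(b_index(f) - 0.247), 0.002)

  expect_equal(b_index(rep("A", 30), n_options = 4), 1)
  expect_equal(b_index(rep(c("A", "B", "C", "D"), 25)), 0)
  expect_error(b_index(c(1, 2), n_options = 1), class = "attnrl_invalid_input")
  expect_error(choice_entropy(c(0, 0)), class = "attnrl_invalid_input")

  set.seed(11)
  for (i in 1:50) {
    counts <- rmultinom(1, 200, prob = runif(4))[, 1]
    b <- b_index(counts, n_options = 4)
    expect_true(b >= 0 && b <= 1)
  }
})

test_that("run extraction partitions the sequence and respects session breaks", {
  expect_equal(extract_runs(strsplit("AAABABBCACD", "")[[1]]),
               c(3, 1, 1, 2, 1, 1, 1, 1))
  expect_equal(extract_runs(rep("Z", 17)), 17)
  expect_equal(extract_runs(rep(c("A", "B"), 10)), rep(1, 20))
  # a session break terminates the current run
  expect_equal(extract_runs(rep("A", 10), sessions = rep(1:2, each = 5)), c(5, 5))
  set.seed(2)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    y <- sample(LETTERS[1:4], n, replace = TRUE)
    s <- sort(sample(1:3, n, replace = TRUE))
    expect_equal(sum(extract_runs(y, s)), n)
  }
})

test_that("sorted reference groups labels into one block each", {
  expect_identical(paste(sorted_reference(strsplit("AAABABBCACD", "")[[1]]),
                         collapse = ""), "AAAAABBBCCD")
  srt <- sorted_reference(c("B", "A", "B"))
  expect_identical(sorted_reference(srt), srt)
  expect_identical(sorted_reference(rep("Q", 5)), rep("Q", 5))
})

test_that("area statistic matches the brute-force integrator", {
  expect_equal(area_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  # hand-computed two-point case: CCDFs (1, 1/3) vs (1, 2/3) on u = (0, ln 2)
  a <- area_statistic(c(1, 1, 2), c(1, 2, 2))
  expect_equal(a, log(2)^2 / 2, tolerance = 1e-12)
  expect_equal(a, naive_area(c(1, 1, 2), c(1, 2, 2)), tolerance = 1e-10)
  set.seed(8)
  for (i in 1:100) {
    l1 <- random_runs(sample(10:200, 1))
    l2 <- random_runs(sample(10:200, 1), lambda = runif(1, 1.1, 4))
    expect_equal(area_statistic(l1, l2), naive_area(l1, l2), tolerance = 1e-10)
    expect_equal(area_statistic(l1, l2), area_statistic(l2, l1))
    expect_gte(area_statistic(l1, l2), 0)
  }
})

test_that("persistence index separates iid, persistent and sorted sequences", {
  # sorted input: numerator and denominator identical by construction
  srt <- fixture_sequences("sorted", n = 400, seed = 3)
  expect_equal(p_index(srt, n_shuffles = 50, seed = 1), 1)

  iid_vals <- purrr::map_dbl(1:20, function(s)
    p_index(fixture_sequences("iid", n = 1500, seed = 1000 + s),
            n_shuffles = 1000, seed = s))
  expect_lt(mean(iid_vals), 0.15)
  expect_lt(sd(iid_vals), 0.02)

  mk_vals <- purrr::map_dbl(1:20, function(s)
    p_index(fixture_sequences("markov_stay", n = 1500, parameter = 0.9,
                              seed = 2000 + s),
            n_shuffles = 200, seed = s))
  expect_true(all(mk_vals > max(iid_vals)))

  # reproducibility and the undefined case
  y <- fixture_sequences("iid", n = 300, seed = 5)
  expect_identical(p_index(y, n_shuffles = 100, seed = 7),
                   p_index(y, n_shuffles = 100, seed = 7))
  expect_error(p_index(rep("A", 50)), class = "attnrl_undefined_index")
})

test_that("continuation probability matches known transition kernels", {
  iid <- fixture_sequences("iid", n = 1e5, seed = 12)
  cp <- continue_probability(iid, max_length = 5)
  expect_true(all(abs(cp$p - 0.25) < 0.02))

  cst <- continue_probability(rep("A", 40))
  expect_true(all(cst$p[cst$n > 0] == 1))

  mk <- fixture_sequences("markov_stay", n = 1e5, parameter = 0.8, seed = 13)
  cpm <- continue_probability(mk, max_length = 6)
  expect_true(all(abs(cpm$p - 0.8) < 0.02))
})

test_that("chi-squared uniformity test matches printed and hand values", {
  # integer counts behind the printed rates at 1,500 trials
  printed <- chi2_uniform(c(149, 399, 878, 74))
  expect_equal(printed$statistic, 1054.0, tolerance = 1 / 1054)
  expect_equal(printed$df, 3)
  expect_lt(printed$p_value, 0.001)
  expect_equal(chi2_uniform(rep(12, 4))$statistic, 0)
  expect_equal(chi2_uniform(c(10, 20, 30, 40))$statistic, 20)
  expect_error(chi2_uniform(c(0, 0, 0)), class = "attnrl_invalid_input")
})

test_that("windowed entropy tracks local choice diversity", {
  w <- windowed_entropy(rep("A", 150), window = 50)
  expect_equal(w$entropy, rep(0, 3))
  expect_false(any(w$partial))

  alt <- windowed_entropy(rep(c("A", "B"), 100), window = 50)
  expect_equal(alt$entropy, rep(log(2), 4))

  iid <- fixture_sequences("iid", n = 1500, seed = 6)
  wi <- windowed_entropy(iid, sessions = rep(1:10, each = 150), window = 50)
  expect_equal(nrow(wi), 30)
  expect_lt(abs(mean(wi$entropy) - log(4)), 0.1)

  tr <- windowed_entropy(rep("A", 120), window = 50)
  expect_identical(tr$partial, c(FALSE, FALSE, TRUE))
  expect_equal(tr$n_trials, c(50, 50, 20))
  expect_error(windowed_entropy(rep("A", 10), window = 1),
               class = "attnrl_invalid_input")
})

test_that("session-wise area comparison is calibrated and has power", {
  sess <- rep(1:10, each = 150)
  # null: data that are themselves exchangeable -> mostly non-significant
  null_p <- purrr::map_dbl(1:20, function(s) {
    y <- fixture_sequences("iid", n = 1500, seed = 4000 + s)
    area_significance(y, sess, n_shuffles = 200, seed = s)$p_value
  })
  expect_gte(sum(null_p > 0.05), 18)
  # power: strongly perseverative sessions
  alt_p <- purrr::map_dbl(1:20, function(s) {
    y <- fixture_sequences("markov_stay", n = 1500, parameter = 0.9, seed = 5000 + s)
    area_significance(y, sess, n_shuffles = 200, seed = s)$p_value
  })
  expect_gte(sum(alt_p < 0.05), 18)
  # degenerate: per-session sorted sequences against the sorted reference
  y0 <- rep(rep(c("A", "B"), each = 75), 4)
  at <- area_significance(y0, rep(1:4, each = 150), reference = "sorted",
                          n_shuffles = 50, seed = 1)
  expect_equal(at$statistic, 0)
  expect_error(area_significance(y0, rep(1, 600)), class = "attnrl_invalid_input")
})
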
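make_am <- function(values, attribute = "a") {
  tibble::tibble(attribute = attribute,
                 option = paste0("o", seq_along(values)),
                 raw = values)
}

test_that("divide-by-max normalization reproduces the calorie and proximity ratios", {
  cal <- normalize_attributes(make_am(c(2.06, 0.78, 0.15, 0.08)))
  expect_equal(cal$value, c(1, 0.78 / 2.06, 0.15 / 2.06, 0.08 / 2.06))
  expect_equal(round(cal$value, 4), c(1, 0.3786, 0.0728, 0.0388))

  prox <- normalize_attributes(make_am(c(1 / 18, 1 / 15, 1 / 15, 1 / 18)))
  expect_equal(round(prox$value, 4), c(0.8333, 1, 1, 0.8333))

  const <- normalize_attributes(make_am(rep(0.15, 4)))
  expect_equal(const$value, rep(1, 4))
})

test_that("normalization preserves within-attribute ordering and rejects bad input", {
  set.seed(1)
  for (i in 1:20) {
    v <- runif(4, 0.01, 5)
    out <- normalize_attributes(make_am(v))
    expect_equal(order(out$value), order(v))
    expect_true(all(out$value > 0 & out$value <= 1))
    expect_equal(max(out$value), 1)
  }
  expect_error(normalize_attributes(make_am(c(-1, -2, -3, 0), "calorie")),
               class = "attnrl_invalid_input")
  expect_error(normalize_attributes(make_am(c(1, NA, 2))),
               class = "attnrl_invalid_input")
})

test_that("preference vector components are attribute ranges with unit geometry", {
  # identical-items condition: only proximity varies, so the vector points at it
  am <- dplyr::bind_rows(
    normalize_attributes(make_am(rep(0.15, 4), "calorie")),
    normalize_attributes(make_am(c(1 / 18, 1 / 15, 1 / 15, 1 / 18), "proximity"))
  )
  pv <- preference_vector(am)
  expect_equal(pv$component, c(0, 1 - 15 / 18))
  expect_equal(round(pv$component[2], 4), 0.1667)
  expect_equal(pv$unit_component, c(0, 1))
  expect_equal(pv$angle_deg, c(90, 0))

  # 3-4-5 triangle
  am2 <- tibble::tibble(
    attribute = rep(c("a", "b"), each = 2),
    option = rep(c("o1", "o2"), 2),
    value = c(0, 3, 0, 4)
  )
  pv2 <- preference_vector(am2)
  expect_equal(attr(pv2, "magnitude"), 5)
  expect_equal(pv2$unit_component, c(0.6, 0.8))

  # degenerate: all options identical
  am3 <- dplyr::bind_rows(normalize_attributes(make_am(rep(1, 4), "a")),
                          normalize_attributes(make_am(rep(2, 4), "b")))
  pv3 <- preference_vector(am3)
  expect_true(attr(pv3, "degenerate"))
  expect_true(all(is.na(pv3$angle_deg)))

  expect_error(preference_vector(am2[c(1, 3), ]), class = "attnrl_invalid_input")
})

test_that("threshold gate switches between selective, divided and degenerate modes", {
  pv_from_ranges <- function(ranges) {
    am <- purrr::imap_dfr(ranges, function(r, i) {
      tibble::tibble(attribute = paste0("k", i), option = c("o1", "o2"),
                     value = c(1 - r, 1))
    })
    preference_vector(am)
  }
  # ranges like the food condition: almost all variation on attribute 1
  w <- attention_weights(pv_from_ranges(c(0.9612, 0.1677)), 30)
  expect_identical(attr(w, "mode"), "selective")
  expect_equal(w$weight, c(1, 0))

  # symmetric ranges never pass a sub-45-degree gate
  w2 <- attention_weights(pv_from_ranges(c(0.3, 0.3)), 30)
  expect_identical(attr(w2, "mode"), "divided")
  expect_equal(w2$weight, rep(1 / sqrt(2), 2), tolerance = 1e-12)

  # degenerate vector: equal weights 1/K
  am0 <- purrr::map_dfr(1:4, function(i)
    tibble::tibble(attribute = paste0("k", i), option = c("o1", "o2"), value = 1))
  w3 <- attention_weights(preference_vector(am0), 30)
  expect_identical(attr(w3, "mode"), "degenerate")
  expect_equal(w3$weight, rep(0.25, 4))

  expect_error(attention_weights(pv_from_ranges(c(0.3, 0.3)), 0),
               class = "attnrl_invalid_config")
  expect_error(attention_weights(pv_from_ranges(c(0.3, 0.3)), 95),
               class = "attnrl_invalid_config")
})

test_that("unit components square-sum to 1 and angles match the dot-product formula", {
  set.seed(42)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    n <- sample(2:5, 1)
    am <- purrr::map_dfr(seq_len(k), function(j)
      tibble::tibble(attribute = paste0("k", j), option = paste0("o", 1:n),
                     value = runif(n)))
    pv <- preference_vector(am)
    if (isTRUE(attr(pv, "degenerate"))) next
    expect_equal(sum(pv$unit_component^2), 1, tolerance = 1e-12)
    # oracle: angle via the full dot product with each attribute axis
    v <- pv$component
    for (j in seq_len(k)) {
      e <- as.numeric(seq_len(k) == j)
      oracle <- acos(sum(v * e) / (sqrt(sum(v^2)) * sqrt(sum(e^2)))) * 180 / pi
      expect_equal(pv$angle_deg[j], oracle, tolerance = 1e-10)
    }
  }
})

test_that("attention weights are invariant to uniform rescaling of the ranges", {
  base <- c(0.8, 0.25, 0.1)
  mk <- function(scale) {
    am <- purrr::imap_dfr(base * scale, function(r, i)
      tibble::tibble(attribute = paste0("k", i), option = c("o1", "o2"),
                     value = c(1 - r, 1)))
    attention_weights(preference_vector(am), 30)
  }
  # note: rescaling the components directly (not renormalized values)
  pv1 <- preference_vector(purrr::imap_dfr(base, function(r, i)
    tibble::tibble(attribute = paste0("k", i), option = c("o1", "o2"), value = c(0, r))))
  pv2 <- preference_vector(purrr::imap_dfr(base * 0.37, function(r, i)
    tibble::tibble(attribute = paste0("k", i), option = c("o1", "o2"), value = c(0, r))))
  w1 <- attention_weights(pv1, 30)
  w2 <- attention_weights(pv2, 30)
  expect_equal(w1$weight, w2$weight, tolerance = 1e-12)
  expect_identical(attr(w1, "mode"), attr(w2, "mode"))
})

test_that("at thresholds up to 45 degrees the selective winner is unique", {
  set.seed(7)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    comps <- runif(k)
    below <- sum(acos(comps / sqrt(sum(comps^2))) * 180 / pi < 45)
    expect_lte(below, 1)
  }
})
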
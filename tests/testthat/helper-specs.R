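# shared fixtures, all built in code

# two-option, one-informative-attribute toy condition for hand-unrolled oracles
toy_spec_2opt <- function() {
  condition_spec(
    condition = 99,
    items = c("A", "B"),
    locations = c("L", "R"),
    distances_cm = c(15, 15),
    attributes = list(
      food = list(type = "item", values = c(A = 1, B = 0.5)),
      proximity = list(type = "location", values = c(L = 1 / 15, R = 1 / 15))
    ),
    session_length = 150, n_sessions = 10
  )
}

# hand-built trial log with a fixed item-to-location assignment
toy_log <- function(items, spec, session = rep(1L, length(items)),
                    assignment = tibble::tibble(session = 1L,
                                                location = spec$locations,
                                                item = spec$items)) {
  loc <- assignment$location[match(items, assignment$item)]
  log <- tibble::tibble(
    session = session,
    trial = unlist(lapply(split(seq_along(items), session), seq_along),
                   use.names = FALSE),
    chosen_option = items,
    chosen_location = loc,
    item_label = items
  )
  attr(log, "assignment") <- assignment
  class(log) <- c("trial_log", class(log))
  log
}

# independent brute-force trapezoid integrator for the area statistic:
# evaluates both floored CCDFs point by point and accumulates segment areas
# in an explicit loop (no shared code with the implementation)
naive_area <- function(l1, l2, floor = 1e-12) {
  xmax <- max(l1, l2)
  P1 <- vapply(1:xmax, function(x) max(mean(l1 >= x), floor), numeric(1))
  P2 <- vapply(1:xmax, function(x) max(mean(l2 >= x), floor), numeric(1))
  u <- log(1:xmax)
  s <- 0
  if (xmax >= 2) {
    for (i in 1:(xmax - 1)) {
      f1 <- abs(log(P1[i]) - log(P2[i]))
      f2 <- abs(log(P1[i + 1]) - log(P2[i + 1]))
      s <- s + (u[i + 1] - u[i]) * (f1 + f2) / 2
    }
  }
  s
}

# random run-length sample with a heavy-ish tail
random_runs <- function(n, lambda = 1.5) {
  pmax(1L, as.integer(rgeom(n, prob = 1 / lambda) + 1L))
}
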
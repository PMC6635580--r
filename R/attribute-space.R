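#' Normalize raw attribute values over a choice set
#'
#' Converts raw, unit-bearing attribute values (kcal per piece, proximity in
#' 1/cm, unitless colour values) to comparable normalized values in (0, 1].
#' The default scheme divides each attribute by its maximum over the choice
#' set, so the best option on an attribute scores 1 and ratios between options
#' are preserved. Min-max scaling is available for sensitivity analyses but
#' note that it forces every varying attribute's range to 1, which flattens
#' the choice-set geometry that the attention gate depends on.
#'
#' @param x A data frame with columns `attribute`, `option` and `raw`
#'   (one row per attribute-option pair).
#' @param scheme Normalization scheme: `"max"` (default, divide by the
#'   attribute's maximum), `"minmax"`, or `"none"` (copy raw values).
#' @return A tibble with the input columns plus `value`, the normalized
#'   attribute value.
#' @examples
#' cal <- tibble::tibble(
#'   attribute = "calorie",
#'   option    = c("PN", "FG", "PL", "KR"),
#'   raw       = c(2.06, 0.78, 0.15, 0.08)
#' )
#' normalize_attributes(cal)
#' @export
normalize_attributes <- function(x, scheme = c("max", "minmax", "none")) {
  scheme <- match.arg(scheme)
  x <- tibble::as_tibble(x)
  required <- c("attribute", "option", "raw")
  if (!all(required %in% names(x))) {
    stop_attnrl(
      paste0("`x` must have columns ", paste(required, collapse = ", ")),
      "attnrl_invalid_input"
    )
  }
  if (any(!is.finite(x$raw))) {
    stop_attnrl("raw attribute values must all be finite", "attnrl_invalid_input")
  }
  x |>
    dplyr::group_by(.data$attribute) |>
    dplyr::group_modify(function(df, key) {
      mx <- max(df$raw)
      if (scheme != "none" && mx <= 0) {
        stop_attnrl(
          sprintf("attribute '%s' has non-positive maximum; cannot normalize", key$attribute),
          "attnrl_invalid_input"
        )
      }
      df$value <- switch(scheme,
        max    = df$raw / mx,
        minmax = if (mx == min(df$raw)) rep(1, nrow(df)) else
          (df$raw - min(df$raw)) / (mx - min(df$raw)),
        none   = df$raw
      )
      df
    }) |>
    dplyr::ungroup()
}

#' Preference vector of a choice set
#'
#' The preference vector connects the point of per-attribute minima to the
#' point of per-attribute maxima of the normalized option values: its
#' component on attribute k is the range `max - min` of normalized values on
#' k. Its direction encodes which attributes most differentiate the options:
#' the unit components are the relative distinctiveness of each attribute,
#' and the angle between the vector and each attribute axis (arccos of the
#' unit component) feeds the attention threshold gate.
#'
#' @param x A normalized attribute table as returned by
#'   [normalize_attributes()] (columns `attribute`, `option`, `value`), with
#'   at least two options.
#' @return A tibble of class `"preference_vector"` with one row per attribute
#'   and columns `component`, `unit_component` and `angle_deg`, plus
#'   attributes `magnitude` and `degenerate`. For a degenerate choice set
#'   (all options identical on all attributes, magnitude 0) the unit
#'   components and angles are `NA`.
#' @examples
#' cond1 <- builtin_condition(1)
#' pv <- preference_vector(attribute_matrix(cond1))
#' pv
#' @export
preference_vector <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("attribute", "option", "value") %in% names(x))) {
    stop_attnrl("`x` must have columns attribute, option, value (run normalize_attributes() first)",
                "attnrl_invalid_input")
  }
  if (length(unique(x$option)) < 2) {
    stop_attnrl("a preference vector needs at least 2 options", "attnrl_invalid_input")
  }
  out <- x |>
    dplyr::group_by(.data$attribute) |>
    dplyr::summarise(component = max(.data$value) - min(.data$value), .groups = "drop")
  magnitude <- sqrt(sum(out$component^2))
  if (magnitude > 0) {
    out$unit_component <- out$component / magnitude
    out$angle_deg <- acos(pmin(1, pmax(-1, out$unit_component))) * 180 / pi
  } else {
    out$unit_component <- NA_real_
    out$angle_deg <- NA_real_
  }
  structure(out,
    magnitude = magnitude,
    degenerate = magnitude == 0,
    class = c("preference_vector", class(out))
  )
}

#' Attention weights from the threshold gate
#'
#' Applies the attention threshold gate to a preference vector. If the
#' smallest angle between the preference vector and an attribute axis falls
#' below `theta_threshold_deg`, attention is selective: that attribute gets
#' weight 1 and all others 0 (ties broken by smallest angle, then attribute
#' order). Otherwise attention is divided and each attribute is weighted by
#' its unit preference-vector component. A degenerate (zero-magnitude)
#' preference vector yields equal weights 1/K, the behaviourally neutral
#' fallback.
#'
#' For thresholds at or below 45 degrees at most one attribute can pass the
#' gate, since at most one unit component can exceed cos(45) = 1/sqrt(2).
#'
#' @param v A [preference_vector()].
#' @param theta_threshold_deg Threshold angle in degrees, strictly between 0
#'   and 90. Default 30.
#' @return A tibble of class `"attention_weights"` with columns `attribute`
#'   and `weight`, and attribute `mode` (`"selective"`, `"divided"` or
#'   `"degenerate"`).
#' @export
attention_weights <- function(v, theta_threshold_deg = 30) {
  if (!inherits(v, "preference_vector")) {
    stop_attnrl("`v` must be a preference_vector", "attnrl_invalid_input")
  }
  if (!is.numeric(theta_threshold_deg) || length(theta_threshold_deg) != 1 ||
      theta_threshold_deg <= 0 || theta_threshold_deg >= 90) {
    stop_attnrl("theta_threshold_deg must lie strictly between 0 and 90 degrees",
                "attnrl_invalid_config")
  }
  out <- tibble::tibble(attribute = v$attribute)
  if (isTRUE(attr(v, "degenerate"))) {
    out$weight <- rep(1 / nrow(v), nrow(v))
    mode <- "degenerate"
  } else if (min(v$angle_deg) < theta_threshold_deg) {
    winner <- order(v$angle_deg)[1]  # smallest angle; order() breaks ties by index
    out$weight <- as.numeric(seq_len(nrow(v)) == winner)
    mode <- "selective"
  } else {
    out$weight <- v$unit_component
    mode <- "divided"
  }
  structure(out, mode = mode, class = c("attention_weights", class(out)))
}

#' @export
print.preference_vector <- function(x, ...) {
  cat(sprintf("<preference_vector> magnitude %.4f%s\n",
              attr(x, "magnitude"),
              if (isTRUE(attr(x, "degenerate"))) " (degenerate)" else ""))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @export
print.attention_weights <- function(x, ...) {
  cat(sprintf("<attention_weights> mode: %s\n", attr(x, "mode")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
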
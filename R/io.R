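trial_log_cols <- c("session", "trial", "chosen_option", "chosen_location", "item_label")

# internal: serializable form of a condition_spec
spec_to_list <- function(spec) {
  list(
    condition = spec$condition,
    items = spec$items,
    locations = spec$locations,
    distances_cm = spec$distances_cm,
    attributes = lapply(spec$attributes, function(a)
      list(type = a$type, values = as.list(a$values))),
    session_length = spec$session_length,
    n_sessions = spec$n_sessions,
    theta_threshold_deg = spec$theta_threshold_deg,
    normalization = spec$normalization,
    index_attribute = spec$index_attribute
  )
}

spec_from_list <- function(x) {
  x$attributes <- lapply(x$attributes, function(a)
    list(type = a$type, values = unlist(a$values)))
  do.call(condition_spec, x)
}

#' Read and write condition specifications as YAML
#'
#' Round-trippable YAML serialization of a [condition_spec()].
#'
#' @param spec A [condition_spec()].
#' @param path File path.
#' @return `write_condition()` returns `path` invisibly; `read_condition()`
#'   returns a [condition_spec()].
#' @export
write_condition <- function(spec, path) {
  stopifnot(inherits(spec, "condition_spec"))
  yaml::write_yaml(spec_to_list(spec), path, precision = 15)
  invisible(path)
}

#' @rdname write_condition
#' @export
read_condition <- function(path) {
  spec_from_list(yaml::read_yaml(path))
}

#' Read and write model parameters as JSON
#'
#' @param params A [model_params()].
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` a
#'   [model_params()].
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  do.call(model_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a trial log as CSV with a JSON sidecar
#'
#' The CSV holds the five trial-log columns (comma-separated, UTF-8, header
#' row); the sidecar `<path minus extension>.json` records everything needed
#' to reproduce or re-analyse the log: generating parameters, seed, variant,
#' condition spec, per-session item-to-location assignment, and a hash of the
#' spec.
#'
#' @param log A trial log tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  if (!all(trial_log_cols %in% names(log))) {
    stop_attnrl(paste0("trial log must have columns ",
                       paste(trial_log_cols, collapse = ", ")), "attnrl_invalid_input")
  }
  readr::write_csv(log[trial_log_cols], path)
  spec <- attr(log, "spec")
  params <- attr(log, "params")
  sidecar <- list(
    params = if (!is.null(params)) unclass(params),
    seed = attr(log, "seed"),
    variant = attr(log, "variant"),
    spec = if (!is.null(spec)) spec_to_list(spec),
    spec_hash = if (!is.null(spec)) rlang::hash(spec_to_list(spec)),
    assignment = attr(log, "assignment")
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[^./]*$", "", path), ".json")

#' Read a trial log written by [write_trial_log()]
#'
#' Strict reader: the header must contain exactly the trial-log columns,
#' `session`/`trial` must parse as integers with each session's trials
#' numbered contiguously from 1, and malformed rows are an error, never
#' coerced. If the JSON sidecar is present the generating parameters, spec
#' and assignment are re-attached.
#'
#' @param path CSV path.
#' @return A `trial_log` tibble.
#' @export
read_trial_log <- function(path) {
  log <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      session = readr::col_integer(),
      trial = readr::col_integer(),
      chosen_option = readr::col_character(),
      chosen_location = readr::col_character(),
      item_label = readr::col_character()
    )
  ))
  probs <- readr::problems(log)
  if (nrow(probs) > 0) {
    stop_attnrl(sprintf("malformed trial log: row %d, column %s",
                        probs$row[1], probs$col[1]), "attnrl_invalid_input")
  }
  if (!identical(sort(names(log)), sort(trial_log_cols))) {
    stop_attnrl("trial log must have exactly the standard columns", "attnrl_invalid_input")
  }
  for (s in unique(log$session)) {
    tr <- log$trial[log$session == s]
    if (!identical(as.integer(tr), seq_along(tr))) {
      stop_attnrl(sprintf("session %d: trial numbers are not contiguous from 1", s),
                  "attnrl_invalid_input")
    }
  }
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(side$params)) attr(log, "params") <- do.call(model_params, side$params)
    if (!is.null(side$spec)) {
      sp <- side$spec
      sp$attributes <- lapply(sp$attributes, function(a)
        list(type = a$type, values = unlist(a$values)))
      attr(log, "spec") <- do.call(condition_spec, sp)
    }
    if (!is.null(side$assignment)) attr(log, "assignment") <- tibble::as_tibble(side$assignment)
    attr(log, "seed") <- side$seed
    attr(log, "variant") <- side$variant
  }
  class(log) <- c("trial_log", class(log))
  log
}
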
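#' Read a configuration file into a parameter bundle
#'
#' Configuration is a YAML mapping with flat dotted keys
#' (`uptake.peak_share: 0.875`), merged over [base_case()]. The special key
#' `uptake.schedule_override` takes a year -> treated-count mapping, or
#' `null` to switch to the parametric logistic uptake. Unknown keys are an
#' error, not a warning: a silently ignored typo would corrupt a scenario
#' comparison. Every override is validated against the bundle invariants.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) config file.
#' @param base Bundle the file overrides; defaults to [base_case()].
#' @return An [scd_parameters] object.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines("uptake.peak_share: 0.875", f)
#' load_config(f)$uptake$peak_share
#' @export
load_config <- function(path, base = base_case()) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "scd_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(base)
  if (!is.list(raw) || is.null(names(raw))) {
    abort("config must be a mapping of dotted keys", class = "scd_config_error")
  }
  apply_overrides(base, raw)
}

apply_overrides <- function(params, overrides) {
  known <- config_keys(params)
  for (key in names(overrides)) {
    if (!key %in% known) {
      abort(sprintf("unknown config key '%s'", key),
            class = "scd_config_error", key = key)
    }
    params <- set_field(params, key, overrides[[key]])
  }
  params$run$end_year <- params$run$start_year + params$run$horizon_years
  params$population$mean_age <- weighted_mean_age(params$population)
  validate_parameters(params)
}

# dotted-path accessors ------------------------------------------------------

split_key <- function(key) strsplit(key, ".", fixed = TRUE)[[1]]

get_field <- function(params, key) {
  node <- params
  for (part in split_key(key)) {
    if (!part %in% names(node)) {
      abort(sprintf("unknown parameter '%s'", key), class = "scd_key_error")
    }
    node <- node[[part]]
  }
  node
}

set_field <- function(params, key, value) {
  parts <- split_key(key)
  node <- params
  for (part in parts[-length(parts)]) node <- node[[part]]
  leaf <- parts[length(parts)]
  if (!leaf %in% names(node) && !identical(parts[1:2], c("uptake", "schedule_override"))) {
    abort(sprintf("unknown parameter '%s'", key), class = "scd_key_error")
  }
  if (identical(key, "uptake.schedule_override")) {
    value <- normalise_schedule(value)
  } else if (is.list(value)) {
    value <- unlist(value)
  }
  params[[parts]] <- value
  params
}

normalise_schedule <- function(value) {
  if (is.null(value)) return(NULL)
  out <- unlist(value)
  storage.mode(out) <- "double"
  if (is.null(names(out)) || anyNA(suppressWarnings(as.integer(names(out))))) {
    abort("uptake.schedule_override must map years to treated counts",
          class = "scd_config_error")
  }
  out[order(as.integer(names(out)))]
}

config_keys <- function(params) {
  flat <- flatten_params(params)
  unique(c(names(flat), "uptake.schedule_override"))
}

flatten_params <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    v <- x[[nm]]
    if (identical(key, "uptake.schedule_override")) {
      out[[key]] <- as.list(v)
    } else if (is.list(v)) {
      out <- c(out, flatten_params(v, key))
    } else if (length(v) > 1 && !is.null(names(v))) {
      for (vn in names(v)) out[[paste(key, vn, sep = ".")]] <- unname(v[[vn]])
    } else {
      out[[key]] <- v
    }
  }
  out
}

#' Serialise a parameter bundle to a config file
#'
#' Writes the flat dotted-key YAML representation of `params`; reading it
#' back with [load_config()] reproduces the bundle exactly (round-trip
#' identity).
#'
#' @param params An [scd_parameters] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  flat <- flatten_params(unclass(params))
  flat <- flat[!vapply(flat, function(v) !is.list(v) && all(is.na(v)), logical(1))]
  # metrics vector: yaml handles lists natively
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Print the fully resolved configuration
#'
#' @param params An [scd_parameters] object.
#' @return The flat key-value representation, invisibly (printed as YAML).
#' @export
print_config <- function(params = base_case()) {
  flat <- flatten_params(unclass(params))
  cat(yaml::as.yaml(flat))
  invisible(flat)
}
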
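#' Sensitivity parameter registry
#'
#' Every population and outcome parameter, plus the uptake peak share, the
#' haemoglobin response parameters, the attenuation-curve shape and the
#' mortality calibration target, is registered for one-way sensitivity
#' analysis. Bounds are the printed brackets where the source tables give
#' them; otherwise base +/- 25% (the stated sensitivity range).
#'
#' @param params An [scd_parameters] object.
#' @return A tibble with columns `param_id`, `base`, `low`, `high`,
#'   `bound_source` (`"printed"` or `"range"`) and `monotone` (whether the
#'   base-case impact is expected to lie between the two bound impacts).
#' @export
parameter_registry <- function(params = base_case()) {
  printed <- printed_bounds(params)
  ids <- c(
    names(printed),
    "hb.sd_delta", "mortality.crude_rate_target",
    "curve.midpoint", "curve.steepness"
  )
  rows <- map(ids, function(id) {
    base <- get_field(params, id)
    if (id %in% names(printed)) {
      b <- printed[[id]]
      src <- "printed"
    } else {
      rng <- params$run$sensitivity_range
      b <- c(base * (1 - rng), base * (1 + rng))
      src <- "range"
    }
    tibble(
      param_id = id, base = base, low = b[1], high = b[2],
      bound_source = src,
      monotone = !id %in% c("curve.midpoint", "curve.steepness", "hb.sd_delta")
    )
  })
  bind_rows(rows)
}

printed_bounds <- function(params) {
  out <- list(
    population.prevalent_n0 = c(4575, 7625),
    population.incident_n0 = c(225, 375),
    population.incident_growth = c(0.038, 0.063),
    `population.age_fractions.12-15` = c(0.113, 0.188),
    `population.age_fractions.16-24` = c(0.188, 0.313),
    `population.age_fractions.25+` = c(0.450, 0.750),
    population.life_expectancy_birth = c(45, 65),
    population.female_fraction = c(0.45, 0.65),
    uptake.peak_share = c(0.525, 0.875),
    hb.mean_delta = c(0.9, 1.4)
  )
  for (o in params$outcomes) {
    out[[sprintf("outcomes.%s.rr_value", o$name)]] <- c(o$rr_low, o$rr_high)
    if (!is.na(o$lifetime_prevalence)) {
      out[[sprintf("outcomes.%s.lifetime_prevalence", o$name)]] <-
        c(o$peer_low, o$peer_high)
    }
  }
  out
}

#' Sensitivity bounds for one parameter
#'
#' Printed table brackets when available, otherwise base +/- 25%. `param_id`
#' is a dotted path (`"uptake.peak_share"`); an unambiguous suffix
#' (`"peak_share"`) is also accepted.
#'
#' @param param_id Parameter identifier.
#' @param params An [scd_parameters] object.
#' @return Numeric `c(low, high)`.
#' @examples
#' sensitivity_bounds("population.prevalent_n0")
#' sensitivity_bounds("outcomes.death.rr_value")
#' @export
sensitivity_bounds <- function(param_id, params = base_case()) {
  reg <- parameter_registry(params)
  id <- resolve_param_id(param_id, reg$param_id)
  row <- reg[reg$param_id == id, ]
  c(low = row$low, high = row$high)
}

resolve_param_id <- function(param_id, known) {
  if (param_id %in% known) return(param_id)
  hits <- known[endsWith(known, paste0(".", param_id)) |
                  vapply(strsplit(known, ".", fixed = TRUE),
                         function(p) p[length(p)] == param_id, logical(1))]
  if (length(hits) == 1) return(hits)
  if (length(hits) == 0) {
    abort(sprintf("unknown parameter '%s'", param_id), class = "scd_key_error")
  }
  abort(sprintf("ambiguous parameter '%s' (matches: %s)", param_id,
                paste(hits, collapse = ", ")), class = "scd_key_error")
}

#' Perturb one parameter of a bundle
#'
#' Returns a copy of `params` with `param_id` set to `value`. Used by the
#' tornado analysis; cross-field invariants (age fractions summing to one,
#' curve midpoint within the response band) are relaxed because one-at-a-time
#' perturbation legitimately breaks them, while domain checks still apply.
#' The derived mean age is recomputed with renormalised age weights.
#'
#' @param params An [scd_parameters] object.
#' @param param_id Dotted parameter identifier (or unambiguous suffix).
#' @param value New value.
#' @param strict Enforce cross-field invariants (default `FALSE`).
#' @return A perturbed [scd_parameters] object.
#' @export
set_parameter <- function(params, param_id, value, strict = FALSE) {
  reg_ids <- parameter_registry(params)$param_id
  id <- tryCatch(resolve_param_id(param_id, reg_ids),
                 error = function(e) param_id)
  out <- set_field(params, id, value)
  out$run$end_year <- out$run$start_year + out$run$horizon_years
  out$population$mean_age <- weighted_mean_age(out$population)
  validate_parameters(out, strict = strict)
  out
}
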
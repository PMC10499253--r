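#' One-way sensitivity of a headline metric
#'
#' Re-runs the two-world comparison with a single parameter set to its low
#' and high sensitivity bounds (all else at base) and records the percent
#' impact of the chosen metric at each bound. Perturbing the haemoglobin
#' response parameters (`hb.mean_delta`, `hb.sd_delta`) switches the
#' response-bin fractions to the analytic normal source, since the fixed
#' printed fractions cannot respond to a parameter change; perturbing the
#' mortality calibration target triggers recalibration of the hazard.
#'
#' @param params A calibrated [scd_parameters] object (calibrated on entry if
#'   needed).
#' @param param_id Registered parameter (dotted id or unambiguous suffix).
#' @param metric One of `"deaths"`, `"strokes"`, `"ph_incident"`,
#'   `"ckd_incident"` (percent impact of the with-world on the cumulative
#'   count), or any metric name from the comparison table.
#' @return A one-row tibble: `param_id`, `low`, `high`, `impact_low`,
#'   `impact_high`, `impact_base`, `spread`.
#' @export
one_way <- function(params, param_id, metric = "deaths") {
  params <- ensure_hazard(params)
  reg <- parameter_registry(params)
  id <- resolve_param_id(param_id, reg$param_id)
  row <- reg[reg$param_id == id, ]
  base_impact <- metric_percent(compare_worlds(params), metric)
  impacts <- map_dbl(c(row$low, row$high), function(v) {
    metric_percent(compare_worlds(perturb(params, id, v)), metric)
  })
  tibble(
    param_id = id, metric = metric,
    low = row$low, high = row$high,
    impact_low = impacts[1], impact_high = impacts[2],
    impact_base = base_impact,
    spread = abs(impacts[2] - impacts[1])
  )
}

perturb <- function(params, id, value) {
  out <- set_parameter(params, id, value, strict = FALSE)
  if (startsWith(id, "hb.")) out$engine$response_source <- "analytic"
  if (id == "mortality.crude_rate_target") out$mortality$annual_hazard <- NA_real_
  out
}

metric_percent <- function(cmp, metric) {
  key <- switch(metric,
    deaths = "deaths", strokes = "strokes",
    ph_incident = "ph_incident", ckd_incident = "ckd_incident",
    metric
  )
  rows <- cmp$comparison[cmp$comparison$metric == key, ]
  if (nrow(rows) != 1) {
    abort(sprintf("unknown metric '%s'", metric), class = "scd_key_error")
  }
  rows$percent
}

#' Tornado analysis
#'
#' One-way deterministic sensitivity over every registered parameter, ranked
#' by descending spread of the metric's percent impact (ties broken
#' lexicographically by parameter id), keeping the `top_n` most impactful.
#'
#' @param params An [scd_parameters] object.
#' @param metric Headline metric (see [one_way()]); default `"deaths"`.
#' @param top_n Number of entries kept (default 10).
#' @return A tibble of class `scd_tornado` ordered by decreasing spread, with
#'   the [one_way()] columns. Supports [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' tornado(base_case(), metric = "strokes", top_n = 5)
#' }
#' @export
tornado <- function(params = base_case(), metric = "deaths", top_n = 10) {
  params <- ensure_hazard(params)
  reg <- parameter_registry(params)
  entries <- map(reg$param_id, function(id) one_way(params, id, metric))
  out <- bind_rows(entries) %>%
    arrange(desc(spread), param_id) %>%
    dplyr::slice_head(n = top_n)
  class(out) <- c("scd_tornado", class(out))
  attr(out, "metric") <- metric
  attr(out, "params") <- params
  out
}
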
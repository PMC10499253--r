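#' Annualise a lifetime event probability
#'
#' Converts a lifetime prevalence `P` over `L` years to the constant annual
#' event probability `r` solving `1 - (1 - r)^L = P`, i.e.
#' `r = 1 - (1 - P)^(1/L)` — the constant-hazard (geometric) convention,
#' which round-trips exactly. The linear convention `r = P / L` is available
#' for comparison; it differs by under 4% at the prevalences modelled here.
#'
#' @param p Lifetime probability in `[0, 1]`.
#' @param life_expectancy Years over which the lifetime risk accrues
#'   (default 55).
#' @param method `"constant_hazard"` (default) or `"linear"`.
#' @return Annual event probability (per person-year).
#' @examples
#' annualize_lifetime_prevalence(0.129, 55)
#' @export
annualize_lifetime_prevalence <- function(p, life_expectancy = 55,
                                          method = c("constant_hazard", "linear")) {
  method <- match.arg(method)
  if (any(p < 0) || any(p > 1)) {
    abort("lifetime probability must lie in [0, 1]", class = "scd_domain_error")
  }
  stopifnot(life_expectancy > 0)
  switch(method,
    constant_hazard = 1 - (1 - p)^(1 / life_expectancy),
    linear = pmin(p / life_expectancy, 1)
  )
}

#' Risk multiplier for a given haemoglobin response
#'
#' The protective effect of treatment is attenuated by the achieved
#' haemoglobin change through a logistic curve:
#' `multiplier(d) = 1 - E_max * plogis(steepness * (d - midpoint))`.
#' Under the default `risk_ratio` semantics the tabulated relative risk `rr`
#' is the rate multiplier reached by full responders, so
#' `E_max = 1 - rr`; under `risk_reduction` semantics `E_max = rr`. The
#' multiplier is strictly decreasing in the response and approaches 1 (no
#' protection) for large negative changes.
#'
#' @param delta_hb Haemoglobin change from baseline, g/dL (vectorised).
#' @param rr_value Tabulated relative risk for the outcome, in (0, 1).
#' @param curve Curve parameters (a list with `midpoint`, `steepness`,
#'   `semantics`); defaults to the base-case curve.
#' @return Rate multiplier in (0, 1].
#' @examples
#' rrr_multiplier(1.1, 0.59)
#' @export
rrr_multiplier <- function(delta_hb, rr_value, curve = base_case()$curve) {
  stopifnot(curve$steepness > 0, rr_value > 0, rr_value < 1)
  e_max <- switch(curve$semantics,
    risk_ratio = 1 - rr_value,
    risk_reduction = rr_value,
    abort("unknown curve semantics", class = "scd_key_error")
  )
  1 - e_max * stats::plogis(curve$steepness * (delta_hb - curve$midpoint))
}

#' Bin-level risk multipliers
#'
#' Evaluates the attenuation curve at the representative response of each
#' bin: non-responders get no effect (`m_low = 1`), partial responders the
#' curve at `mid_bin_eval` (0.9 g/dL — the curve midpoint, hence half the
#' maximum effect), full responders the curve at `high_bin_eval` (far enough
#' up the curve that the full tabulated relative risk is realised to within
#' 1e-3).
#'
#' @param rr_value Tabulated relative risk for the outcome.
#' @param curve Curve parameters; defaults to the base-case curve.
#' @return Named numeric `c(m_low, m_mid, m_high)` with
#'   `m_low >= m_mid >= m_high`.
#' @examples
#' bin_multipliers(0.36) # death row: c(1, 0.68, ~0.36)
#' @export
bin_multipliers <- function(rr_value, curve = base_case()$curve) {
  c(
    m_low = 1,
    m_mid = rrr_multiplier(curve$mid_bin_eval, rr_value, curve),
    m_high = rrr_multiplier(curve$high_bin_eval, rr_value, curve)
  )
}

#' Coverage-weighted effective annual rate
#'
#' Composes the baseline annual rate with treatment coverage and the
#' response-stratified multipliers:
#' `rate = baseline * ((1 - c) + c * (f_low * m_low + f_mid * m_mid + f_high * m_high))`.
#' Untreated patients (`1 - c`) keep the baseline rate; treated patients are
#' weighted across the response bins.
#'
#' @param baseline_rate Annual event probability without treatment.
#' @param coverage Treated share of the population, in `[0, 1]` (vectorised).
#' @param dist Response distribution (one-row tibble from
#'   [response_distribution()] or a numeric `c(f_low, f_mid, f_high)`).
#' @param multipliers Named numeric `c(m_low, m_mid, m_high)` from
#'   [bin_multipliers()].
#' @return Effective annual rate, never exceeding `baseline_rate`.
#' @examples
#' effective_annual_rate(0.01, 0.5, c(0.18, 0.195, 0.625), c(1, 0.7, 0.59))
#' @export
effective_annual_rate <- function(baseline_rate, coverage, dist, multipliers) {
  if (is.data.frame(dist)) dist <- c(dist$f_low, dist$f_mid, dist$f_high)
  stopifnot(all(coverage >= 0), all(coverage <= 1), length(dist) == 3)
  treated_mult <- sum(dist * multipliers[c("m_low", "m_mid", "m_high")])
  baseline_rate * ((1 - coverage) + coverage * treated_mult)
}

#' Annual risk table for all outcomes
#'
#' Baseline annual rates (from lifetime prevalences annualised over the life
#' expectancy at birth; the death hazard from the calibrated mortality
#' parameters) together with the bin multipliers per outcome.
#'
#' @param params An [scd_parameters] object.
#' @return A tibble with columns `outcome`, `lifetime_prevalence`,
#'   `annual_rate`, `m_low`, `m_mid`, `m_high`.
#' @examples
#' risk_table(base_case())
#' @export
risk_table <- function(params = base_case()) {
  params <- ensure_hazard(params)
  le <- params$population$life_expectancy_birth
  rows <- map(params$outcomes, function(o) {
    rate <- if (o$name == "death") {
      params$mortality$annual_hazard
    } else {
      annualize_lifetime_prevalence(o$lifetime_prevalence, le,
                                    params$engine$annualization)
    }
    m <- bin_multipliers(o$rr_value, params$curve)
    tibble(
      outcome = o$name,
      lifetime_prevalence = o$lifetime_prevalence,
      annual_rate = rate,
      m_low = m[["m_low"]], m_mid = m[["m_mid"]], m_high = m[["m_high"]]
    )
  })
  bind_rows(rows)
}
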
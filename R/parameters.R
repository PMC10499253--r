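#' Model parameter bundle
#'
#' An `scd_parameters` object collects every quantity the projection model
#' needs, grouped the way the model uses them:
#'
#' * `population`: prevalent patients at inception, incident patients per
#'   year and their annual growth, the age mix (three groups: 12-15, 16-24,
#'   25+ years), overall life expectancy at birth, and the female fraction.
#'   The age-group means, overall mean age and female fraction are carried as
#'   descriptors; only the mean age is functional (it seeds the baseline
#'   prevalent complication pools).
#' * `outcomes`: one row per modelled complication (`death`, `stroke`, `PH`,
#'   `CKD`) holding the lifetime prevalence (absent for death), the relative
#'   risk associated with a >= 1 g/dL haemoglobin increase, and the printed
#'   sensitivity bounds for both.
#' * `uptake`: launch year, peak market share, time to peak, ramp horizon,
#'   and an optional explicit year -> treated-count schedule (the default
#'   anchors: 305, 1308, 3358, 4857, 5473, 5803 for 2023-2028).
#' * `hb`: the haemoglobin response distribution (mean change +1.1 g/dL,
#'   SD 0.40), the responder thresholds (0.8 and 1.0 g/dL), and the size and
#'   seed of the simulated patient sample.
#' * `curve`: the logistic attenuation curve that maps achieved haemoglobin
#'   change to realised risk reduction (midpoint, steepness, evaluation
#'   points for the middle and top response bins, and the semantics under
#'   which the tabulated relative risks are interpreted).
#' * `mortality`: baseline annual death hazard (calibrated when `NA` to the
#'   crude-rate target) and the life-expectancy extrapolation mode.
#' * `engine`: structural switches — how the mortality benefit is applied
#'   (`"population"`: all treated patients receive the full death risk
#'   ratio; `"stratified"`: response-bin weighting as for the morbidity
#'   channels), whether baseline prevalent pools are seeded from
#'   age-accumulated risk, how many entrant cohorts arrive (6 yearly cohorts
#'   by default), the annualisation convention, and the source of the
#'   response-bin fractions (`"printed"`, `"analytic"`, `"simulated"`).
#' * `run`: start year, horizon and sensitivity range.
#'
#' @param population,outcomes,uptake,hb,curve,mortality,engine,run Named
#'   lists overriding individual fields of the base case; see Details.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `scd_parameters`.
#' @seealso [base_case()], [load_config()], [sensitivity_bounds()]
#' @export
scd_parameters <- function(population = list(), outcomes = list(),
                           uptake = list(), hb = list(), curve = list(),
                           mortality = list(), engine = list(), run = list(),
                           validate = TRUE) {
  p <- default_parameters()
  p$population <- utils::modifyList(p$population, population)
  for (nm in names(outcomes)) {
    if (!nm %in% names(p$outcomes)) {
      abort(sprintf("unknown outcome '%s'", nm), class = "scd_config_error")
    }
    p$outcomes[[nm]] <- utils::modifyList(p$outcomes[[nm]], outcomes[[nm]])
  }
  p$uptake <- utils::modifyList(p$uptake, uptake)
  p$hb <- utils::modifyList(p$hb, hb)
  p$curve <- utils::modifyList(p$curve, curve)
  p$mortality <- utils::modifyList(p$mortality, mortality)
  p$engine <- utils::modifyList(p$engine, engine)
  p$run <- utils::modifyList(p$run, run)
  p$run$end_year <- p$run$start_year + p$run$horizon_years
  p$population$mean_age <- weighted_mean_age(p$population)
  class(p) <- "scd_parameters"
  if (validate) validate_parameters(p)
  p
}

default_parameters <- function() {
  list(
    population = list(
      prevalent_n0 = 6100,
      incident_n0 = 300,
      incident_growth = 0.05,
      age_fractions = c(`12-15` = 0.15, `16-24` = 0.25, `25+` = 0.60),
      age_means = c(`12-15` = 13.5, `16-24` = 20.0, `25+` = 33.0),
      mean_age = 26.8,
      life_expectancy_birth = 55.0,
      female_fraction = 0.55
    ),
    outcomes = list(
      death = list(
        name = "death", lifetime_prevalence = NA_real_,
        rr_value = 0.36, rr_low = 0.27, rr_high = 0.45,
        peer_low = NA_real_, peer_high = NA_real_, chronic_flag = "terminal"
      ),
      stroke = list(
        name = "stroke", lifetime_prevalence = 0.129,
        rr_value = 0.59, rr_low = 0.44, rr_high = 0.74,
        peer_low = 0.097, peer_high = 0.161, chronic_flag = "acute"
      ),
      PH = list(
        name = "PH", lifetime_prevalence = 0.490,
        rr_value = 0.43, rr_low = 0.32, rr_high = 0.54,
        peer_low = 0.368, peer_high = 0.613, chronic_flag = "chronic"
      ),
      CKD = list(
        name = "CKD", lifetime_prevalence = 0.266,
        rr_value = 0.47, rr_low = 0.35, rr_high = 0.59,
        peer_low = 0.200, peer_high = 0.333, chronic_flag = "chronic"
      )
    ),
    uptake = list(
      launch_year = 2023,
      peak_share = 0.70,
      time_to_peak = 3,
      ramp_horizon = 5,
      schedule_override = c(
        `2023` = 305, `2024` = 1308, `2025` = 3358,
        `2026` = 4857, `2027` = 5473, `2028` = 5803
      ),
      # peak share under which the override counts were generated; when
      # peak_share is perturbed the counts scale by peak_share / this value
      schedule_peak_share = 0.70,
      post_ramp_policy = "hold_share"
    ),
    hb = list(
      mean_delta = 1.1, sd_delta = 0.40,
      threshold_low = 0.8, threshold_high = 1.0,
      n_patients = 1000L, seed = 42L
    ),
    curve = list(
      midpoint = 0.9, steepness = 25,
      semantics = "risk_ratio",
      mid_bin_eval = 0.9, high_bin_eval = 1.3
    ),
    mortality = list(
      annual_hazard = NA_real_,
      crude_rate_target = 0.00971,
      extrapolation_mode = "baseline_hazard"
    ),
    engine = list(
      death_effect = "population",
      seed_prevalence = TRUE,
      entrant_years = 6,
      annualization = "constant_hazard",
      response_source = "printed"
    ),
    run = list(
      start_year = 2023, horizon_years = 20, end_year = 2043,
      sensitivity_range = 0.25,
      metrics = c("deaths", "strokes", "ph_incident", "ckd_incident")
    )
  )
}

weighted_mean_age <- function(pop) {
  w <- pop$age_fractions
  sum(w * pop$age_means) / sum(w)
}

#' Base-case parameter bundle
#'
#' The canonical French base case: 6,100 prevalent patients (2022), 300
#' incident patients per year growing at 5%, age mix 15/25/60%, life
#' expectancy at birth 55 years, 55% female; complication lifetime
#' prevalences 12.9% (stroke), 49.0% (PH), 26.6% (CKD) with relative risks
#' 0.59/0.43/0.47 and 0.36 for death; uptake peaking at a 70% market share
#' after 3 years with the treated-patient schedule 305...5803 over
#' 2023-2028; haemoglobin response +1.1 +/- 0.40 g/dL binned at 0.8 and
#' 1.0 g/dL.
#'
#' @return An [scd_parameters] object.
#' @examples
#' p <- base_case()
#' p$population$prevalent_n0
#' p$outcomes$stroke$rr_value
#' @export
base_case <- function() scd_parameters()

#' Validate a parameter bundle
#'
#' Checks the type and cross-field invariants. With `strict = FALSE` the
#' cross-field checks that a one-at-a-time sensitivity perturbation may
#' legitimately break (age fractions summing to one, life expectancy
#' exceeding mean age) are skipped; domain checks always apply.
#'
#' @param params An [scd_parameters] object.
#' @param strict Enforce cross-field invariants (default `TRUE`).
#' @return `params`, invisibly; aborts with class `scd_validation_error`
#'   naming the offending field otherwise.
#' @export
validate_parameters <- function(params, strict = TRUE) {
  fail <- function(field, msg) {
    abort(sprintf("invalid parameter '%s': %s", field, msg),
          class = "scd_validation_error", field = field)
  }
  pop <- params$population
  if (!is.numeric(pop$prevalent_n0) || pop$prevalent_n0 <= 0) {
    fail("population.prevalent_n0", "must be a positive count")
  }
  if (!is.numeric(pop$incident_n0) || pop$incident_n0 < 0) {
    fail("population.incident_n0", "must be a non-negative count")
  }
  if (any(pop$age_fractions < 0 | pop$age_fractions > 1)) {
    fail("population.age_fractions", "each fraction must lie in [0, 1]")
  }
  if (strict && abs(sum(pop$age_fractions) - 1) > 1e-9) {
    fail("population.age_fractions", "must sum to 1")
  }
  if (pop$female_fraction < 0 || pop$female_fraction > 1) {
    fail("population.female_fraction", "must lie in [0, 1]")
  }
  if (pop$life_expectancy_birth <= 0) {
    fail("population.life_expectancy_birth", "must be positive")
  }
  if (strict && pop$life_expectancy_birth <= pop$mean_age) {
    fail("population.life_expectancy_birth", "must exceed the mean age")
  }
  for (o in params$outcomes) {
    id <- paste0("outcomes.", o$name)
    if (!is.na(o$lifetime_prevalence) &&
        (o$lifetime_prevalence < 0 || o$lifetime_prevalence > 1)) {
      fail(paste0(id, ".lifetime_prevalence"), "must lie in [0, 1]")
    }
    if (o$rr_value <= 0 || o$rr_value >= 1) {
      fail(paste0(id, ".rr_value"), "must lie in (0, 1)")
    }
    if (strict && !(o$rr_low <= o$rr_value && o$rr_value <= o$rr_high)) {
      fail(paste0(id, ".rr_value"), "must lie within [rr_low, rr_high]")
    }
  }
  up <- params$uptake
  if (up$peak_share <= 0 || up$peak_share > 1) {
    fail("uptake.peak_share", "must lie in (0, 1]")
  }
  if (strict && up$time_to_peak > up$ramp_horizon) {
    fail("uptake.time_to_peak", "must not exceed the ramp horizon")
  }
  hb <- params$hb
  if (hb$sd_delta <= 0) fail("hb.sd_delta", "must be positive")
  if (hb$threshold_low >= hb$threshold_high) {
    fail("hb.threshold_low", "must be below hb.threshold_high")
  }
  if (hb$n_patients < 1) fail("hb.n_patients", "must be at least 1")
  cv <- params$curve
  if (cv$steepness <= 0) fail("curve.steepness", "must be positive")
  if (strict && (cv$midpoint < hb$threshold_low ||
                 cv$midpoint > hb$threshold_high)) {
    fail("curve.midpoint", "must lie between the response thresholds")
  }
  if (!cv$semantics %in% c("risk_ratio", "risk_reduction")) {
    fail("curve.semantics", "must be 'risk_ratio' or 'risk_reduction'")
  }
  mt <- params$mortality
  if (!is.na(mt$annual_hazard) &&
      (mt$annual_hazard <= 0 || mt$annual_hazard >= 1)) {
    fail("mortality.annual_hazard", "must lie in (0, 1)")
  }
  if (mt$crude_rate_target <= 0 || mt$crude_rate_target >= 1) {
    fail("mortality.crude_rate_target", "must lie in (0, 1)")
  }
  if (!mt$extrapolation_mode %in%
      c("baseline_hazard", "effective_hazard", "none")) {
    fail("mortality.extrapolation_mode", "unknown extrapolation mode")
  }
  en <- params$engine
  if (!en$death_effect %in% c("population", "stratified")) {
    fail("engine.death_effect", "must be 'population' or 'stratified'")
  }
  if (!en$annualization %in% c("constant_hazard", "linear")) {
    fail("engine.annualization", "unknown annualisation convention")
  }
  if (!en$response_source %in% c("printed", "analytic", "simulated")) {
    fail("engine.response_source", "unknown response source")
  }
  if (en$entrant_years < 0 || en$entrant_years > params$run$horizon_years) {
    fail("engine.entrant_years", "must lie within the horizon")
  }
  rn <- params$run
  if (rn$end_year != rn$start_year + rn$horizon_years) {
    fail("run.end_year", "must equal start_year + horizon_years")
  }
  if (!is.null(up$schedule_override)) {
    yrs <- as.integer(names(up$schedule_override))
    if (anyNA(yrs)) fail("uptake.schedule_override", "years must be integers")
    if (any(up$schedule_override < 0)) {
      fail("uptake.schedule_override", "treated counts must be non-negative")
    }
  }
  invisible(params)
}

#' @export
print.scd_parameters <- function(x, ...) {
  cat("<scd_parameters>\n")
  cat(sprintf("  population : %s prevalent, %s incident/yr (+%.1f%%/yr), %d entrant cohorts\n",
              format(x$population$prevalent_n0), format(x$population$incident_n0),
              100 * x$population$incident_growth, x$engine$entrant_years))
  cat(sprintf("  horizon    : %d-%d\n", x$run$start_year, x$run$end_year))
  cat(sprintf("  uptake     : peak %.0f%%, %s\n", 100 * x$uptake$peak_share,
              if (is.null(x$uptake$schedule_override)) "parametric logistic"
              else "explicit treated schedule"))
  cat(sprintf("  Hb response: %+.1f +/- %.2f g/dL, bins at %.1f/%.1f (%s fractions)\n",
              x$hb$mean_delta, x$hb$sd_delta, x$hb$threshold_low,
              x$hb$threshold_high, x$engine$response_source))
  haz <- if (is.na(x$mortality$annual_hazard)) {
    sprintf("calibrated to crude rate %.3f%%/py", 100 * x$mortality$crude_rate_target)
  } else {
    sprintf("%.6f/py", x$mortality$annual_hazard)
  }
  cat(sprintf("  mortality  : %s; death effect '%s'\n", haz, x$engine$death_effect))
  rrs <- map_dbl(x$outcomes, "rr_value")
  cat(sprintf("  risk ratios: %s\n",
              paste(sprintf("%s %.2f", names(rrs), rrs), collapse = ", ")))
  invisible(x)
}
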
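#' Run one counterfactual world
#'
#' Advances the population year by year with deterministic expected-value
#' arithmetic (no Monte Carlo). Each annual cycle: (1) the year's entrant
#' cohort arrives (first `entrant_years` years only; cohort size grows at the
#' incident growth rate); (2) treatment coverage is read off the uptake
#' schedule (zero in the `"without"` world); (3) deaths are removed at the
#' coverage-weighted effective hazard; (4) incident complications occur among
#' survivors at coverage-weighted effective rates — pulmonary hypertension
#' and chronic kidney disease move survivors into absorbing prevalent pools
#' (which are themselves depleted by mortality), stroke is counted as a
#' recurrent event with no state change; (5) life-years accrue with half-cycle
#' correction, and life-years with complication accrue from the prevalent
#' pools. Baseline prevalent pools are seeded at inception from
#' age-accumulated risk when `engine$seed_prevalence` is set.
#'
#' @param params An [scd_parameters] object; a missing baseline hazard is
#'   calibrated first (see [calibrate_mortality()]).
#' @param world `"without"` or `"with"` (treatment availability).
#' @return A tibble ledger of class `scd_ledger`, one row per projection
#'   year: population, coverage, deaths, incident events, prevalent pools and
#'   life-year accumulators.
#' @examples
#' run_world(base_case(), "without")
#' @export
run_world <- function(params, world = c("without", "with")) {
  world <- match.arg(world)
  params <- ensure_hazard(params)
  engine_run(params, world, params$mortality$annual_hazard)
}

engine_run <- function(params, world, hazard) {
  pop <- params$population
  en <- params$engine
  rn <- params$run
  up <- params$uptake
  le <- pop$life_expectancy_birth

  dist <- response_distribution(params)
  f <- c(dist$f_low, dist$f_mid, dist$f_high)
  morb <- c("stroke", "PH", "CKD")
  rates <- map_dbl(params$outcomes[morb], function(o) {
    annualize_lifetime_prevalence(o$lifetime_prevalence, le, en$annualization)
  })
  w_treated <- map_dbl(params$outcomes[morb], function(o) {
    sum(f * bin_multipliers(o$rr_value, params$curve))
  })
  w_death <- if (en$death_effect == "population") {
    params$outcomes$death$rr_value
  } else {
    sum(f * bin_multipliers(params$outcomes$death$rr_value, params$curve))
  }

  # uptake: explicit schedule scaled to the peak share (the default counts
  # realise the base 70% peak), or the fitted parametric logistic
  ov <- up$schedule_override
  peak_scale <- up$peak_share / up$schedule_peak_share
  if (is.null(ov)) {
    fit <- fit_uptake_anchors(default_share_anchors(), cap = up$peak_share)
  }

  years <- seq(rn$start_year, rn$end_year - 1)
  n <- length(years)
  alive <- pop$prevalent_n0
  pool <- c(PH = 0, CKD = 0)
  if (isTRUE(en$seed_prevalence)) {
    pool <- alive * (1 - (1 - rates[c("PH", "CKD")])^pop$mean_age)
    names(pool) <- c("PH", "CKD")
  }
  hold_share <- NA_real_
  cols <- c("alive_start", "entrants", "treated", "coverage", "deaths",
            "stroke_incident", "ph_incident", "ckd_incident", "ph_prevalent",
            "ckd_prevalent", "life_years", "life_years_ph", "life_years_ckd",
            "alive_end")
  acc <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))

  for (i in seq_len(n)) {
    y <- years[i]
    t <- y - rn$start_year
    entrants <- if (t < en$entrant_years) pop$incident_n0 * (1 + pop$incident_growth)^t else 0
    alive <- alive + entrants

    cov <- 0
    if (world == "with") {
      if (!is.null(ov)) {
        ykey <- as.character(y)
        if (ykey %in% names(ov)) {
          cov <- peak_scale * ov[[ykey]] / alive
          if (y == max(as.integer(names(ov)))) hold_share <- cov
        } else if (y > max(as.integer(names(ov)))) {
          cov <- hold_share
        }
      } else if (y >= up$launch_year) {
        cov <- logistic_share(y - up$launch_year, up$peak_share,
                              fit$steepness, fit$midpoint)
      }
      cov <- min(max(cov, 0), 1)
    }

    m_death <- (1 - cov) + cov * w_death
    deaths <- alive * hazard * m_death
    life_years <- alive - deaths / 2
    surv <- alive - deaths
    pool <- pool * (1 - hazard * m_death)

    m_morb <- (1 - cov) + cov * w_treated
    at_risk <- c(stroke = surv, PH = surv - pool[["PH"]],
                 CKD = surv - pool[["CKD"]])
    events <- at_risk * rates * m_morb
    pool <- pool + events[c("PH", "CKD")]

    state <- c(alive, surv, pool, events, deaths)
    if (any(state < -1e-9)) {
      abort("internal consistency error: negative state", class = "scd_internal_error")
    }

    acc[i, ] <- c(alive, entrants, cov * alive, cov, deaths,
                  events[["stroke"]], events[["PH"]], events[["CKD"]],
                  pool[["PH"]], pool[["CKD"]], life_years,
                  pool[["PH"]], pool[["CKD"]], surv)
    alive <- surv
  }

  ledger <- bind_cols(tibble(year = years), as_tibble(acc))
  class(ledger) <- c("scd_ledger", class(ledger))
  attr(ledger, "world") <- world
  attr(ledger, "params") <- params
  ledger
}

#' Calibrate the baseline mortality hazard
#'
#' The source tables give life expectancy and lifetime prevalences but no
#' annual death rate; the reproducible anchor is the crude death rate the
#' projected ledger implies (cumulative deaths divided by cumulative
#' life-years in the untreated world; 0.971% per person-year in the base
#' case). The hazard is found by root-solving the full engine so the
#' untreated world's crude rate matches the target exactly.
#'
#' @param params An [scd_parameters] object.
#' @param target Crude death rate per person-year, in (0, 1); defaults to
#'   `params$mortality$crude_rate_target`.
#' @param tol Convergence tolerance on the crude rate (default 1e-10).
#' @return `params` with `mortality$annual_hazard` set.
#' @examples
#' p <- calibrate_mortality(base_case())
#' p$mortality$annual_hazard
#' @export
calibrate_mortality <- function(params, target = NULL, tol = 1e-10) {
  target <- target %||% params$mortality$crude_rate_target
  if (!is.numeric(target) || target <= 0 || target >= 1) {
    abort("crude-rate target must lie in (0, 1)", class = "scd_domain_error")
  }
  crude <- function(lambda) {
    led <- engine_run(params, "without", lambda)
    sum(led$deaths) / sum(led$life_years) - target
  }
  root <- tryCatch(
    uniroot(crude, lower = target / 4, upper = min(4 * target, 0.99),
            tol = tol, extendInt = "upX"),
    error = function(e) {
      abort(sprintf("mortality calibration failed: %s", conditionMessage(e)),
            class = "scd_calibration_error")
    }
  )
  params$mortality$annual_hazard <- root$root
  params
}

ensure_hazard <- function(params) {
  if (is.na(params$mortality$annual_hazard)) calibrate_mortality(params) else params
}

#' Lifetime life expectancy from a projection ledger
#'
#' Expected years per member of the inception-plus-entrant population:
#' within-horizon person-years divided by the total population, plus an
#' extrapolation for horizon-end survivors. `"baseline_hazard"` (default)
#' credits survivors with `1 / hazard` remaining years at the calibrated
#' untreated hazard — the treatment effect is confined to the horizon;
#' `"effective_hazard"` uses the final-year coverage-weighted hazard of the
#' ledger's own world; `"none"` truncates at the horizon.
#'
#' @param ledger An `scd_ledger` from [run_world()].
#' @param params Parameter bundle; defaults to the one attached to the
#'   ledger.
#' @param extrapolation Override the bundle's extrapolation mode.
#' @return Life expectancy in years.
#' @export
life_expectancy <- function(ledger, params = attr(ledger, "params"),
                            extrapolation = NULL) {
  extrapolation <- extrapolation %||% params$mortality$extrapolation_mode
  params <- ensure_hazard(params)
  hazard <- params$mortality$annual_hazard
  n_total <- params$population$prevalent_n0 + sum(ledger$entrants)
  survivors <- ledger$alive_end[nrow(ledger)]
  remaining <- switch(extrapolation,
    none = 0,
    baseline_hazard = 1 / hazard,
    effective_hazard = {
      cov <- ledger$coverage[nrow(ledger)]
      w_death <- if (params$engine$death_effect == "population") {
        params$outcomes$death$rr_value
      } else {
        dist <- response_distribution(params)
        sum(c(dist$f_low, dist$f_mid, dist$f_high) *
              bin_multipliers(params$outcomes$death$rr_value, params$curve))
      }
      1 / (hazard * ((1 - cov) + cov * w_death))
    },
    abort("unknown extrapolation mode", class = "scd_key_error")
  )
  (sum(ledger$life_years) + survivors * remaining) / n_total
}

#' Compare the two counterfactual worlds
#'
#' Runs both worlds on the same calibrated bundle and tabulates the headline
#' metrics: cumulative deaths, life-years, lifetime life expectancy,
#' cumulative incident strokes, prevalent pulmonary-hypertension and
#' chronic-kidney-disease cases at the horizon end, cumulative incident
#' cases of each, and life-years spent with each complication. The percent
#' impact is the absolute impact relative to the untreated world, sign
#' preserved.
#'
#' @param params An [scd_parameters] object.
#' @return An object of class `scd_comparison`: a list with the two ledgers
#'   (`$without`, `$with`), the comparison tibble (`$comparison`) and the
#'   calibrated bundle (`$params`). Supports [tidy()], [glance()],
#'   [ggplot2::autoplot()] and `print()`.
#' @examples
#' cmp <- compare_worlds(base_case())
#' cmp$comparison
#' @export
compare_worlds <- function(params = base_case()) {
  params <- ensure_hazard(params)
  wo <- engine_run(params, "without", params$mortality$annual_hazard)
  wi <- engine_run(params, "with", params$mortality$annual_hazard)
  last <- nrow(wo)
  metric_rows <- list(
    deaths = c(sum(wo$deaths), sum(wi$deaths)),
    life_years = c(sum(wo$life_years), sum(wi$life_years)),
    life_expectancy = c(life_expectancy(wo), life_expectancy(wi)),
    strokes = c(sum(wo$stroke_incident), sum(wi$stroke_incident)),
    ph_prevalent_end = c(wo$ph_prevalent[last], wi$ph_prevalent[last]),
    ckd_prevalent_end = c(wo$ckd_prevalent[last], wi$ckd_prevalent[last]),
    ph_incident = c(sum(wo$ph_incident), sum(wi$ph_incident)),
    ckd_incident = c(sum(wo$ckd_incident), sum(wi$ckd_incident)),
    life_years_ph = c(sum(wo$life_years_ph), sum(wi$life_years_ph)),
    life_years_ckd = c(sum(wo$life_years_ckd), sum(wi$life_years_ckd))
  )
  comparison <- bind_rows(imap(metric_rows, function(v, nm) {
    tibble(
      metric = nm, without = v[1], with = v[2],
      impact = v[2] - v[1],
      percent = 100 * (v[2] - v[1]) / v[1]
    )
  }))
  structure(
    list(without = wo, with = wi, comparison = comparison, params = params),
    class = "scd_comparison"
  )
}

#' @export
print.scd_comparison <- function(x, ...) {
  cat(sprintf("<scd_comparison> %d-%d, two counterfactual worlds\n",
              x$params$run$start_year, x$params$run$end_year))
  df <- as.data.frame(x$comparison)
  df$without <- round(df$without, 1)
  df$with <- round(df$with, 1)
  df$impact <- round(df$impact, 1)
  df$percent <- sprintf("%+.1f%%", df$percent)
  print(df, row.names = FALSE)
  invisible(x)
}
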
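#' Logistic adoption and diffusion share
#'
#' Sigmoid market-share curve
#' `share(t) = peak_share / (1 + exp(-steepness * (t - midpoint)))`, the
#' standard diffusion form: monotone in `t`, bounded above by `peak_share`,
#' and equal to half the peak at `t = midpoint`.
#'
#' @param t Years since launch (vectorised).
#' @param peak_share Maximum market share at peak, in (0, 1].
#' @param steepness Diffusion speed, per year; must be positive.
#' @param midpoint Year (since launch) at which half the peak is reached.
#' @return Treated share of the population, same length as `t`.
#' @examples
#' logistic_share(0:5, peak_share = 0.7, steepness = 1.76, midpoint = 1.46)
#' @export
logistic_share <- function(t, peak_share, steepness, midpoint) {
  stopifnot(steepness > 0)
  peak_share / (1 + exp(-steepness * (t - midpoint)))
}

#' Fit the logistic uptake curve to share anchors
#'
#' With two anchors the fit is the exact two-point inversion
#' `logit(share / cap) = steepness * (t - midpoint)`; with more, an ordinary
#' least-squares line on the logit scale (residuals are reported on the share
#' scale).
#'
#' @param anchors Data frame with columns `t` (years since launch) and
#'   `share`, or a named numeric vector `c("0" = 0.05, "2" = 0.505)`.
#' @param cap Upper asymptote (peak share). All anchor shares must lie
#'   strictly inside `(0, cap)`.
#' @return A list with `steepness`, `midpoint`, `cap`, `fitted` and
#'   `residuals` (share scale).
#' @examples
#' fit_uptake_anchors(c("0" = 0.05, "2" = 0.505), cap = 0.70)
#' @export
fit_uptake_anchors <- function(anchors, cap = 0.70) {
  if (is.numeric(anchors) && !is.null(names(anchors))) {
    anchors <- tibble(t = as.numeric(names(anchors)), share = unname(anchors))
  }
  anchors <- as_tibble(anchors)
  stopifnot(all(c("t", "share") %in% names(anchors)))
  if (nrow(anchors) < 2 || length(unique(anchors$t)) < 2) {
    abort("at least 2 anchors with distinct times are required",
          class = "scd_domain_error")
  }
  if (any(anchors$share <= 0 | anchors$share >= cap)) {
    abort("anchor shares must lie strictly inside (0, cap)",
          class = "scd_domain_error")
  }
  z <- stats::qlogis(anchors$share / cap)
  if (nrow(anchors) == 2) {
    steepness <- diff(z) / diff(anchors$t)
    midpoint <- anchors$t[1] - z[1] / steepness
  } else {
    fit <- stats::lm(z ~ anchors$t)
    steepness <- unname(stats::coef(fit)[2])
    midpoint <- -unname(stats::coef(fit)[1]) / steepness
  }
  if (!is.finite(steepness) || steepness <= 0) {
    abort("anchors do not define a rising logistic", class = "scd_domain_error")
  }
  fitted <- logistic_share(anchors$t, cap, steepness, midpoint)
  list(
    steepness = steepness, midpoint = midpoint, cap = cap,
    fitted = fitted, residuals = anchors$share - fitted
  )
}

#' Year-by-year treated-patient schedule
#'
#' Builds the uptake schedule over the projection horizon. With an explicit
#' `schedule_override` (the default: the 2023-2028 treated counts
#' 305, 1308, 3358, 4857, 5473, 5803) the printed counts are used verbatim
#' and the implied treated share of the final override year is held constant
#' afterwards. Without an override, the parametric logistic fitted to the
#' default share anchors is evaluated and counts are `round(share * alive)`.
#'
#' Two share conventions coexist and both are reported: `share` relates the
#' treated count to the start-of-year population before that year's entrant
#' cohort (the convention in which the launch-year share is exactly
#' 305 / 6100 = 5.0%), while `coverage` relates it to the population the
#' engine exposes to risk, which includes the entrants.
#'
#' @param params An [scd_parameters] object.
#' @param population Optional tibble with columns `year`, `alive_pre_entrants`
#'   and `alive` (population at risk). Defaults to the bundle's own
#'   untreated-world trajectory.
#' @return A tibble with columns `year`, `treated`, `share`, `coverage`.
#' @examples
#' build_schedule(base_case())
#' @export
build_schedule <- function(params, population = NULL) {
  if (is.null(population)) {
    led <- run_world(params, world = "without")
    population <- tibble(
      year = led$year,
      alive_pre_entrants = led$alive_start - led$entrants,
      alive = led$alive_start
    )
  }
  ov <- params$uptake$schedule_override
  up <- params$uptake
  n <- nrow(population)
  treated <- numeric(n)
  if (!is.null(ov)) {
    ov_years <- as.integer(names(ov))
    hold_share <- NA_real_
    for (i in seq_len(n)) {
      y <- population$year[i]
      if (y %in% ov_years) {
        treated[i] <- ov[[as.character(y)]]
        hold_share <- treated[i] / population$alive[i]
      } else if (y > max(ov_years) && !is.na(hold_share)) {
        treated[i] <- hold_share * population$alive[i]
      }
    }
  } else {
    fit <- fit_uptake_anchors(default_share_anchors(), cap = up$peak_share)
    t <- population$year - up$launch_year
    sh <- ifelse(t < 0, 0, logistic_share(t, up$peak_share, fit$steepness, fit$midpoint))
    treated <- round(sh * population$alive)
  }
  bad <- treated > population$alive + 1e-9
  if (any(bad)) {
    abort(sprintf("treated count exceeds alive population in %s",
                  paste(population$year[bad], collapse = ", ")),
          class = "scd_validation_error")
  }
  tibble(
    year = population$year,
    treated = treated,
    share = treated / population$alive_pre_entrants,
    coverage = treated / population$alive
  )
}

# launch-year and mid-ramp share anchors used for the parametric mode: ~5% of
# the eligible population in the launch year and half coverage two years in.
default_share_anchors <- function() c(`0` = 0.05, `2` = 0.505)
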
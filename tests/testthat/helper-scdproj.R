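# shared fixtures: small deterministic bundles built in code

# bundle with an explicitly fixed hazard (skips calibration) and no pools,
# convenient for closed-form checks
fixed_hazard_params <- function(hazard = 0.01, ...) {
  p <- scd_parameters(...)
  p$mortality$annual_hazard <- hazard
  p
}

# single closed cohort: no entrants, no seeded pools, no uptake
single_cohort_params <- function(n0 = 6100, hazard = 0.01, horizon = 20) {
  p <- fixed_hazard_params(
    hazard,
    population = list(prevalent_n0 = n0, incident_n0 = 0),
    engine = list(entrant_years = 0, seed_prevalence = FALSE),
    run = list(horizon_years = horizon,
               end_year = 2023 + horizon)
  )
  p
}

# uptake schedule with all-zero treated counts over the ramp
zero_uptake_params <- function() {
  sched <- setNames(rep(0, 6), 2023:2028)
  scd_parameters(uptake = list(schedule_override = sched))
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")

# canonical flat representation for bundle equality checks
flatten_unclassed <- function(p) scdproj:::flatten_params(unclass(p))
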
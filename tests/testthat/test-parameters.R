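test_that("base case carries the tabulated population and outcome inputs", {
  p <- base_case()
  expect_identical(p$population$prevalent_n0, 6100)
  expect_identical(p$population$incident_n0, 300)
  expect_identical(p$population$incident_growth, 0.05)
  expect_equal(unname(p$population$age_fractions), c(0.15, 0.25, 0.60))
  expect_equal(sum(p$population$age_fractions), 1)
  expect_equal(p$population$mean_age, 26.8, tolerance = 0.002)
  expect_identical(p$population$life_expectancy_birth, 55)
  expect_identical(p$population$female_fraction, 0.55)

  rr <- vapply(p$outcomes, `[[`, numeric(1), "rr_value")
  expect_equal(rr, c(death = 0.36, stroke = 0.59, PH = 0.43, CKD = 0.47))
  peer <- vapply(p$outcomes, `[[`, numeric(1), "lifetime_prevalence")
  expect_equal(unname(peer[c("stroke", "PH", "CKD")]), c(0.129, 0.490, 0.266))
  expect_true(is.na(peer[["death"]]))

  expect_identical(p$uptake$peak_share, 0.70)
  expect_identical(p$uptake$time_to_peak, 3)
  expect_equal(unname(p$uptake$schedule_override),
               c(305, 1308, 3358, 4857, 5473, 5803))
  expect_identical(p$hb$mean_delta, 1.1)
  expect_identical(p$hb$sd_delta, 0.40)
  expect_identical(c(p$hb$threshold_low, p$hb$threshold_high), c(0.8, 1.0))
  expect_identical(p$run$end_year, 2043)
})

test_that("invariant violations abort naming the offending field", {
  expect_error(scd_parameters(hb = list(sd_delta = -1)),
               "hb.sd_delta", class = "scd_validation_error")
  expect_error(scd_parameters(population = list(prevalent_n0 = 0)),
               "prevalent_n0", class = "scd_validation_error")
  expect_error(scd_parameters(outcomes = list(stroke = list(rr_value = 1.2))),
               "rr_value", class = "scd_validation_error")
  expect_error(
    scd_parameters(population = list(age_fractions = c(`12-15` = 0.5, `16-24` = 0.5, `25+` = 0.5))),
    "age_fractions", class = "scd_validation_error"
  )
  expect_error(scd_parameters(curve = list(semantics = "odds")),
               "semantics", class = "scd_validation_error")
})

test_that("empty config file reproduces the base case", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines("", f)
  expect_identical(flatten_unclassed(load_config(f)), flatten_unclassed(base_case()))
})

test_that("config overrides merge over the base case and are validated", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines("uptake.peak_share: 0.875", f)
  p <- load_config(f)
  expect_identical(p$uptake$peak_share, 0.875)
  expect_identical(p$population$prevalent_n0, 6100)

  writeLines("hb.sd_delta: -1", f)
  expect_error(load_config(f), "hb.sd_delta", class = "scd_validation_error")

  writeLines("uptake.peak_shar: 0.8", f)
  expect_error(load_config(f), "unknown config key", class = "scd_config_error")

  expect_error(load_config(tempfile()), class = "scd_io_error")
})

test_that("config round-trips through serialisation", {
  p <- scd_parameters(
    uptake = list(peak_share = 0.6),
    outcomes = list(stroke = list(rr_value = 0.5)),
    engine = list(response_source = "analytic")
  )
  f <- withr::local_tempfile(fileext = ".yml")
  write_config(p, f)
  q <- load_config(f)
  expect_identical(flatten_unclassed(q), flatten_unclassed(p))
})

test_that("schedule override can be replaced or removed via config", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("uptake.schedule_override:", "  2023: 100", "  2024: 200"), f)
  p <- load_config(f)
  expect_equal(unname(p$uptake$schedule_override), c(100, 200))

  writeLines("uptake.schedule_override: null", f)
  p <- load_config(f)
  expect_null(p$uptake$schedule_override)
})

test_that("sensitivity bounds return printed brackets, else +/-25%", {
  expect_equal(unname(sensitivity_bounds("population.prevalent_n0")),
               c(4575, 7625))
  expect_equal(unname(sensitivity_bounds("outcomes.death.rr_value")),
               c(0.27, 0.45))
  expect_equal(unname(sensitivity_bounds("hb.sd_delta")),
               c(0.30, 0.50))
  expect_equal(unname(sensitivity_bounds("peak_share")), c(0.525, 0.875))
  expect_error(sensitivity_bounds("no_such_param"), class = "scd_key_error")
})

test_that("printed brackets agree with the +/-25% rule where they follow it", {
  reg <- parameter_registry(base_case())
  printed <- reg[reg$bound_source == "printed", ]
  # three registered brackets deliberately differ from +/-25%:
  # life expectancy at birth (45-65) and female fraction (0.45-0.65) are
  # printed at +/-18%, and the haemoglobin mean-change bounds (0.9-1.4)
  # come from the sensitivity text, not the 25% rule
  irregular <- c("population.life_expectancy_birth",
                 "population.female_fraction", "hb.mean_delta")
  regular <- printed[!printed$param_id %in% irregular, ]
  expect_gt(nrow(regular), 10)
  expect_equal(regular$low / regular$base, rep(0.75, nrow(regular)),
               tolerance = 0.012)
  expect_equal(regular$high / regular$base, rep(1.25, nrow(regular)),
               tolerance = 0.012)
})

test_that("set_parameter perturbs a copy and relaxes cross-field invariants", {
  p <- base_case()
  q <- set_parameter(p, "uptake.peak_share", 0.525)
  expect_identical(q$uptake$peak_share, 0.525)
  expect_identical(p$uptake$peak_share, 0.70)
  # age fraction perturbation breaks sum-to-1 but is allowed non-strictly,
  # and the derived mean age is recomputed from renormalised weights
  q <- set_parameter(p, "population.age_fractions.25+", 0.75)
  expect_equal(unname(q$population$age_fractions[["25+"]]), 0.75)
  expect_gt(q$population$mean_age, p$population$mean_age)
  expect_error(set_parameter(p, "hb.sd_delta", -0.1),
               class = "scd_validation_error")
})
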